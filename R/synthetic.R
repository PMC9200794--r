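# Synthetic labeled FASTA generator. Emulates the shape of the real datasets
# the pipeline targets (a positive set plus several same-sized negative
# batches) with class-dependent gapped-pattern enrichment, composition
# shifts, and an optional period-3 bias feeding the spectral feature family.

#' Synthetic dataset configuration
#'
#' Defaults mirror the protein-shaped study design: 182 positives and 4
#' negative batches of 185 (`preset = "lncrna"` gives 137 positives, 8
#' batches of 141). Sequences are i.i.d. draws from a per-class base
#' composition; planted left-gap-right patterns are inserted at
#' Poisson-distributed per-sequence counts with class-dependent rates
#' (insertion overwrites background, so sequence length is class-independent);
#' an optional period-3 G bias modulates every third position.
#'
#' @param preset `"protein"` (182/4x185) or `"lncrna"` (137/8x141); individual
#'   arguments override the preset.
#' @param n_pos number of positive sequences.
#' @param n_neg_batches number of negative batches.
#' @param batch_size sequences per negative batch.
#' @param length_range integer (min, max) sequence length in bases.
#' @param base_probs_pos,base_probs_neg per-class background composition
#'   (A, C, G, T), each summing to 1.
#' @param patterns data frame with columns left, gap, right, rate_pos,
#'   rate_neg: planted gapped patterns and their per-sequence Poisson rates.
#' @param period3 named numeric `c(pos=, neg=)` in \[0, 1\]: strength of a G
#'   bias at every third position (0 = off).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(preset = c("protein", "lncrna"),
                         n_pos = NULL, n_neg_batches = NULL, batch_size = NULL,
                         length_range = c(200L, 400L),
                         base_probs_pos = c(A = 0.25, C = 0.25, G = 0.25,
                                            T = 0.25),
                         base_probs_neg = c(A = 0.25, C = 0.25, G = 0.25,
                                            T = 0.25),
                         patterns = default_patterns(),
                         period3 = c(pos = 0, neg = 0),
                         seed = 1L) {
  preset <- match.arg(preset)
  shape <- if (preset == "protein") c(182L, 4L, 185L) else c(137L, 8L, 141L)
  n_pos <- n_pos %||% shape[1]
  n_neg_batches <- n_neg_batches %||% shape[2]
  batch_size <- batch_size %||% shape[3]
  stopifnot(abs(sum(base_probs_pos) - 1) < 1e-12,
            abs(sum(base_probs_neg) - 1) < 1e-12,
            length_range[1] <= length_range[2])
  span <- max(nchar(patterns$left) + patterns$gap + nchar(patterns$right), 0)
  if (length_range[1] < span)
    stop("minimum length ", length_range[1],
         " smaller than largest planted-pattern span ", span)
  structure(list(preset = preset, n_pos = n_pos,
                 n_neg_batches = n_neg_batches, batch_size = batch_size,
                 length_range = as.integer(length_range),
                 base_probs_pos = base_probs_pos,
                 base_probs_neg = base_probs_neg,
                 patterns = patterns, period3 = period3,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted patterns
#'
#' Two gapped patterns enriched in positives (per-sequence Poisson rates 3.0
#' vs 0.2 and 2.5 vs 0.3), giving the k-gap feature family a strong,
#' known-truth signal.
#' @return data frame with columns left, gap, right, rate_pos, rate_neg.
#' @export
default_patterns <- function() {
  data.frame(left = c("AC", "GGA"), gap = c(3L, 1L), right = c("GT", "TC"),
             rate_pos = c(3.0, 2.5), rate_neg = c(0.2, 0.3),
             stringsAsFactors = FALSE)
}

.kgap_family_name <- function(a, b) {
  pre <- c("mono", "di", "tri")
  paste0(pre[a], c("Mono", "Di", "Tri")[b], "KGap")
}

.pattern_feature_names <- function(patterns) {
  if (nrow(patterns) == 0) return(character(0))
  as.character(mapply(function(l, g, r) {
    paste0(.kgap_family_name(nchar(l), nchar(r)), "_g", g, "_", l, "_", r)
  }, patterns$left, patterns$gap, patterns$right, USE.NAMES = FALSE))
}

.gen_one <- function(L, probs, patterns, rates, p3) {
  s <- sample(.BASES, L, replace = TRUE, prob = probs)
  if (p3 > 0) {
    at <- seq(3, L, by = 3)
    flip <- at[stats::runif(length(at)) < p3]
    s[flip] <- "G"
  }
  for (pi in seq_len(nrow(patterns))) {
    cnt <- stats::rpois(1, rates[pi])
    if (cnt == 0) next
    l <- patterns$left[pi]; r <- patterns$right[pi]; g <- patterns$gap[pi]
    span <- nchar(l) + g + nchar(r)
    starts <- sample.int(L - span + 1, cnt, replace = TRUE)
    for (st in starts) {
      s[st:(st + nchar(l) - 1)] <- strsplit(l, "")[[1]]
      s[(st + nchar(l) + g):(st + span - 1)] <- strsplit(r, "")[[1]]
    }
  }
  paste(s, collapse = "")
}

#' Generate a synthetic labeled dataset
#'
#' @param cfg a [synth_config()].
#' @return a `generated_dataset`: list with `positives` (a
#'   [fasta_dataset()]), `negatives` (list of [fasta_dataset()] batches),
#'   `truth` (canonical names of the planted k-gap features), and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rand_len <- function(n) {
    if (cfg$length_range[1] == cfg$length_range[2])
      rep(cfg$length_range[1], n)
    else sample(cfg$length_range[1]:cfg$length_range[2], n, replace = TRUE)
  }
  gen_class <- function(n, probs, rates, p3, ids) {
    lens <- rand_len(n)
    fasta_dataset(
      id = ids,
      residues = vapply(lens, .gen_one, character(1), probs = probs,
                        patterns = cfg$patterns, rates = rates, p3 = p3),
      source = "synthetic")
  }
  pos <- gen_class(cfg$n_pos, cfg$base_probs_pos, cfg$patterns$rate_pos,
                   cfg$period3[["pos"]],
                   sprintf("pos_%04d", seq_len(cfg$n_pos)))
  pos$label <- "positive"
  negatives <- lapply(seq_len(cfg$n_neg_batches), function(b) {
    ds <- gen_class(cfg$batch_size, cfg$base_probs_neg, cfg$patterns$rate_neg,
                    cfg$period3[["neg"]],
                    sprintf("neg%d_%04d", b, seq_len(cfg$batch_size)))
    ds$label <- "negative"
    ds
  })
  structure(list(positives = pos, negatives = negatives,
                 truth = .pattern_feature_names(cfg$patterns), config = cfg),
            class = "generated_dataset")
}

#' Shuffle class membership of a generated dataset
#'
#' Sequences are untouched; the assignment of records to the positive set and
#' the negative batches is permuted uniformly, preserving all set sizes. Used
#' as the null-model fixture: a pipeline run on the result should score near
#' AUC 0.5.
#'
#' @param gd a `generated_dataset`.
#' @param seed permutation seed.
#' @return a `generated_dataset` with permuted membership.
#' @export
permute_labels <- function(gd, seed = 1L) {
  stopifnot(inherits(gd, "generated_dataset"))
  all_res <- c(gd$positives$residues,
               unlist(lapply(gd$negatives, `[[`, "residues")))
  all_ids <- c(gd$positives$id, unlist(lapply(gd$negatives, `[[`, "id")))
  set.seed(seed)
  perm <- sample(length(all_res))
  res <- all_res[perm]
  n_pos <- nrow(gd$positives)
  sizes <- vapply(gd$negatives, nrow, integer(1))
  pos <- fasta_dataset(id = gd$positives$id, residues = res[seq_len(n_pos)],
                       label = "positive", source = "synthetic-permuted")
  off <- n_pos
  negatives <- lapply(seq_along(sizes), function(b) {
    idx <- off + seq_len(sizes[b])
    off <<- off + sizes[b]
    fasta_dataset(id = gd$negatives[[b]]$id, residues = res[idx],
                  label = "negative", source = "synthetic-permuted")
  })
  structure(list(positives = pos, negatives = negatives,
                 truth = character(0), config = gd$config),
            class = "generated_dataset")
}

#' Write a generated dataset to FASTA plus ground-truth JSON
#'
#' Writes `positives.fa`, `negatives_<b>.fa` and `truth.json` (labels,
#' planted feature names, config echo) under `dir`.
#'
#' @param gd a `generated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(gd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(gd$positives, file.path(dir, "positives.fa"))
  for (b in seq_along(gd$negatives))
    write_fasta(gd$negatives[[b]], file.path(dir,
                                             sprintf("negatives_%d.fa", b)))
  cfg <- gd$config
  cfg$patterns <- as.list(cfg$patterns)
  jsonlite::write_json(
    list(truth = gd$truth, config = unclass(cfg),
         n_pos = nrow(gd$positives),
         batch_sizes = vapply(gd$negatives, nrow, integer(1))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
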
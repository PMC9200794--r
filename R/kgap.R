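# Composition / gapped k-mer feature generator: the 13-block, 14,891-feature
# space (at K = 3, n = 5) over the DNA alphabet.

.BASES <- c("A", "C", "G", "T")

.KGAP_FAMILIES <- data.frame(
  name = c("monoMonoKGap", "monoDiKGap", "monoTriKGap", "diMonoKGap",
           "diDiKGap", "diTriKGap", "triMonoKGap", "triDiKGap"),
  a = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
  b = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L),
  stringsAsFactors = FALSE
)

# All words of length `len`, lexicographic A<C<G<T (first character most
# significant; expand.grid varies its first factor fastest, so feed it the
# last character first).
.lex_words <- function(len) {
  g <- do.call(expand.grid, c(replicate(len, .BASES, simplify = FALSE),
                              list(stringsAsFactors = FALSE)))
  do.call(paste0, g[, rev(seq_len(len)), drop = FALSE])
}

#' Feature schema of the composition / k-gap space
#'
#' Canonically ordered, named feature list. Blocks, in fixed order:
#' `zcurve` (3), `gccontent` (1), `atgc_ratio` (1), `cumulative_skew` (2),
#' `pseudo_composition` (sum of 4^o for o = 1..K), then the eight k-gap
#' families monoMono, monoDi, monoTri, diMono, diDi, diTri, triMono, triDi,
#' each of size 4^a * 4^b * n. At the defaults K = 3, n = 5 the total is
#' 14,891. k-gap feature names read `<family>_g<gap>_<left>_<right>`; within a
#' family the gap ascends in the outer loop, then left and right words
#' lexicographically (A<C<G<T).
#'
#' @param K longest subsequence length for pseudo-composition (default 3).
#' @param n largest gap (default 5).
#' @return list with `names` (character vector), `blocks` (data frame of block
#'   name and size) and the `K`, `n` used.
#' @export
pyfeat_schema <- function(K = 3L, n = 5L) {
  stopifnot(K >= 1, n >= 1)
  pc_names <- unlist(lapply(seq_len(K),
                            function(o) paste0("pseudo_", .lex_words(o))))
  blocks <- data.frame(
    block = c("zcurve", "gccontent", "atgc_ratio", "cumulative_skew",
              "pseudo_composition", .KGAP_FAMILIES$name),
    size = c(3L, 1L, 1L, 2L, length(pc_names),
             4L^.KGAP_FAMILIES$a * 4L^.KGAP_FAMILIES$b * n),
    stringsAsFactors = FALSE
  )
  kgap_names <- unlist(lapply(seq_len(nrow(.KGAP_FAMILIES)), function(fi) {
    a <- .KGAP_FAMILIES$a[fi]; b <- .KGAP_FAMILIES$b[fi]
    lw <- .lex_words(a); rw <- .lex_words(b)
    unlist(lapply(seq_len(n), function(g)
      paste0(.KGAP_FAMILIES$name[fi], "_g", g, "_",
             rep(lw, each = length(rw)), "_", rw)))
  }))
  nm <- c("zcurve_x", "zcurve_y", "zcurve_z", "gc_content", "atgc_ratio",
          "gc_skew", "at_skew", pc_names, kgap_names)
  list(names = nm, blocks = blocks, K = K, n = n)
}

#' Terminal Z-curve coordinates
#'
#' The cumulative Z-curve evaluated at the final position L:
#' x = (A+G)-(C+T), y = (A+C)-(G+T), z = (A+T)-(C+G) with total base counts.
#'
#' @param residues an A/C/G/T string.
#' @return named numeric vector `(x, y, z)`.
#' @export
zcurve_terminal <- function(residues) {
  ch <- encode_sequence(residues, "zcurve")$channels
  c(x = unname(ch[nrow(ch), 1]), y = unname(ch[nrow(ch), 2]),
    z = unname(ch[nrow(ch), 3]))
}

.base_counts <- function(residues) {
  s <- .seq_to_int(residues)
  c(A = sum(s == 0L), C = sum(s == 1L), G = sum(s == 2L), T = sum(s == 3L))
}

#' GC content (percent)
#'
#' 100 * (G + C) / (A + C + G + T).
#' @param residues an A/C/G/T string.
#' @return percentage in \[0, 100\].
#' @export
gc_content <- function(residues) {
  n <- .base_counts(residues)
  100 * (n["G"] + n["C"]) / sum(n)
}

#' AT/GC ratio
#'
#' (A + T) / (G + C). Undefined when the sequence has no G or C; then `NA`
#' is returned with a warning (the record is flagged, not errored, so feature
#' matrices stay rectangular).
#' @param residues an A/C/G/T string.
#' @return a real, or `NA` when G + C = 0.
#' @export
atgc_ratio <- function(residues) {
  n <- .base_counts(residues)
  if (n["G"] + n["C"] == 0) {
    warning("atgc_ratio undefined (G + C = 0); recorded as NA")
    return(NA_real_)
  }
  unname((n["A"] + n["T"]) / (n["G"] + n["C"]))
}

#' Cumulative GC and AT skews
#'
#' gc_skew = (G - C) / (G + C), at_skew = (A - T) / (A + T); a zero
#' denominator yields 0 by convention.
#' @param residues an A/C/G/T string.
#' @return named numeric vector `(gc_skew, at_skew)`.
#' @export
cumulative_skew <- function(residues) {
  n <- .base_counts(residues)
  gc <- if (n["G"] + n["C"] > 0) (n["G"] - n["C"]) / (n["G"] + n["C"]) else 0
  at <- if (n["A"] + n["T"] > 0) (n["A"] - n["T"]) / (n["A"] + n["T"]) else 0
  c(gc_skew = unname(gc), at_skew = unname(at))
}

#' Pseudo-composition block
#'
#' Overlapping occurrence counts of every word of length 1..K, ordered by
#' length ascending then lexicographically. Words longer than the sequence
#' count 0.
#' @param residues an A/C/G/T string.
#' @param K longest word length.
#' @return numeric vector of length sum of 4^o, o = 1..K.
#' @export
pseudo_composition <- function(residues, K = 3L) {
  cpp_word_counts(.seq_to_int(residues), as.integer(K))
}

#' One gapped k-mer family block
#'
#' Counts of patterns left-word, g wildcard bases, right-word, for g = 1..n
#' (gap ascending in the outer loop, then left and right words lexicographic).
#' @param residues an A/C/G/T string.
#' @param a left word length (1-3).
#' @param b right word length (1-3).
#' @param n largest gap.
#' @return numeric vector of length 4^a * 4^b * n.
#' @export
kgap_block <- function(residues, a, b, n = 5L) {
  ok <- any(.KGAP_FAMILIES$a == a & .KGAP_FAMILIES$b == b)
  if (!ok) stop("unsupported k-gap family (a=", a, ", b=", b, ")")
  cpp_kgap_counts(.seq_to_int(residues), as.integer(a), as.integer(b),
                  as.integer(n))
}

#' Full composition / k-gap feature vector of one sequence
#'
#' Concatenation of all 13 blocks in schema order; 14,891 features at the
#' defaults. Counts are raw overlapping occurrences (set
#' `normalize = TRUE` to divide each count by its number of possible
#' placements, max(L - span + 1, 0)).
#'
#' @param residues an A/C/G/T string.
#' @param K pseudo-composition max word length.
#' @param n largest gap.
#' @param normalize divide counts by the number of possible placements?
#' @return named numeric vector aligned to [pyfeat_schema()].
#' @export
pyfeat_vector <- function(residues, K = 3L, n = 5L, normalize = FALSE) {
  s <- .seq_to_int(residues)
  L <- length(s)
  pc <- cpp_word_counts(s, as.integer(K))
  kg <- unlist(lapply(seq_len(nrow(.KGAP_FAMILIES)), function(fi) {
    cpp_kgap_counts(s, .KGAP_FAMILIES$a[fi], .KGAP_FAMILIES$b[fi],
                    as.integer(n))
  }))
  if (normalize) {
    spans_pc <- rep(seq_len(K), times = 4L^seq_len(K))
    pc <- pc / pmax(L - spans_pc + 1, 1)
    spans_kg <- unlist(lapply(seq_len(nrow(.KGAP_FAMILIES)), function(fi) {
      a <- .KGAP_FAMILIES$a[fi]; b <- .KGAP_FAMILIES$b[fi]
      rep(a + seq_len(n) + b, each = 4L^a * 4L^b)
    }))
    kg <- kg / pmax(L - spans_kg + 1, 1)
  }
  v <- c(zcurve_terminal(residues), gc_content(residues),
         suppressWarnings(atgc_ratio(residues)), cumulative_skew(residues),
         pc, kg)
  names(v) <- pyfeat_schema(K, n)$names
  v
}

#' Composition / k-gap feature matrix for a dataset
#'
#' One row per record. Records with undefined `atgc_ratio` carry `NA` in that
#' column; the affected ids are attached as attribute `"flagged"`.
#'
#' @param ds a [fasta_dataset()] (sanitized).
#' @param K,n,normalize as in [pyfeat_vector()].
#' @return numeric matrix (rownames = record ids) with attribute `"schema"`.
#' @export
pyfeat_features <- function(ds, K = 3L, n = 5L, normalize = FALSE) {
  stopifnot(inherits(ds, "fasta_dataset"))
  schema <- pyfeat_schema(K, n)
  m <- t(vapply(ds$residues, pyfeat_vector, numeric(length(schema$names)),
                K = K, n = n, normalize = normalize, USE.NAMES = FALSE))
  rownames(m) <- ds$id
  colnames(m) <- schema$names
  attr(m, "schema") <- schema
  attr(m, "flagged") <- ds$id[is.na(m[, "atgc_ratio"])]
  m
}

#' Serialize a feature schema to JSON
#'
#' @param schema a [pyfeat_schema()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(schema[c("blocks", "K", "n", "names")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
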
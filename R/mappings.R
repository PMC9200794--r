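# Five numerical DNA encodings, their DFT power spectra, and the 18-statistic
# spectral descriptor vector ("RFF" feature family).

.SCHEMES <- c("binary", "integer", "real", "zcurve", "eiip")

.DESCRIPTOR_NAMES <- c("papr", "snr", "min", "max", "median", "sd_pop",
                       "sd_samp", "p15", "p25", "p50", "p75", "var", "cv",
                       "amplitude", "semi_iqr", "iqr", "skewness", "kurtosis")

.seq_to_int <- function(residues) {
  v <- match(strsplit(residues, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(v)) stop("sequence contains non-ACGT characters; sanitize first")
  v - 1L
}

#' Numerically encode a DNA sequence
#'
#' Maps an A/C/G/T string to one of five real-valued signal representations:
#' * `binary`: four 0/1 indicator channels, one per base, ordered (A, C, G, T);
#' * `integer`: T=0, C=1, A=2, G=3;
#' * `real`: A=-1.5, G=-0.5, C=0.5, T=1.5;
#' * `zcurve`: cumulative x = (A+G)-(C+T) (purine/pyrimidine),
#'   y = (A+C)-(G+T) (amino/keto), z = (A+T)-(C+G) (weak/strong H bonds),
#'   where letter counts are cumulative over positions 1..l;
#' * `eiip`: electron-ion interaction pseudopotentials G=0.0806, A=0.1260,
#'   T=0.1335, C=0.1340.
#'
#' @param residues an A/C/G/T string (or a single-row [fasta_dataset()]).
#' @param scheme one of `"binary"`, `"integer"`, `"real"`, `"zcurve"`, `"eiip"`.
#' @return A `numeric_signal`: list with `scheme` and `channels`, an L x c
#'   matrix (c = 4 for binary, 3 for zcurve, 1 otherwise).
#' @export
encode_sequence <- function(residues, scheme = .SCHEMES) {
  if (inherits(residues, "fasta_dataset")) residues <- residues$residues[1]
  scheme <- match.arg(scheme)
  if (!nzchar(residues)) stop("empty sequence")
  s <- .seq_to_int(residues)   # A=0 C=1 G=2 T=3
  L <- length(s)
  channels <- switch(scheme,
    binary = {
      m <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
      m[cbind(seq_len(L), s + 1L)] <- 1
      m
    },
    integer = matrix(c(2, 1, 3, 0)[s + 1L], ncol = 1),
    real = matrix(c(-1.5, 0.5, -0.5, 1.5)[s + 1L], ncol = 1),
    zcurve = {
      A <- cumsum(s == 0L); C <- cumsum(s == 1L)
      G <- cumsum(s == 2L); T <- cumsum(s == 3L)
      cbind(x = (A + G) - (C + T),
            y = (A + C) - (G + T),
            z = (A + T) - (C + G))
    },
    eiip = matrix(c(0.1260, 0.1340, 0.0806, 0.1335)[s + 1L], ncol = 1)
  )
  structure(list(scheme = scheme, channels = channels),
            class = "numeric_signal")
}

#' Power spectrum of a numeric signal
#'
#' Squared DFT magnitudes per frequency bin, summed across channels for the
#' multi-channel encodings (binary, Z-curve). No zero-padding: the spectrum has
#' exactly L bins, DC included.
#'
#' @param sig a `numeric_signal` from [encode_sequence()].
#' @return numeric vector `P[f]`, f = 0..L-1 (length L).
#' @export
power_spectrum <- function(sig) {
  stopifnot(inherits(sig, "numeric_signal"))
  ft <- stats::mvfft(sig$channels)
  rowSums(Mod(ft)^2)
}

#' Spectral descriptors of a power spectrum
#'
#' The 18 summary statistics of the power values: peak-to-average power ratio
#' (PAPR = max/mean), SNR (ratio of the period-3 bin `P[round(L/3)]`, 0-based,
#' to the mean), min, max, median, population and sample standard deviation,
#' percentiles 15/25/50/75 (linear interpolation), sample variance,
#' coefficient of variation (population sd / mean), amplitude (max - min),
#' semi-interquartile range, interquartile range, skewness and (non-excess)
#' kurtosis (standardized 3rd/4th central moments).
#'
#' @param ps numeric power spectrum of length >= 2.
#' @param drop_dc drop the f = 0 bin before computing statistics? Default
#'   `FALSE` (all bins used).
#' @return named numeric vector of length 18.
#' @export
spectral_descriptors <- function(ps, drop_dc = FALSE) {
  L <- length(ps)
  if (L < 2) stop("spectrum too short: sample standard deviation undefined")
  snr_bin <- ps[round(L / 3) + 1L]   # period-3 bin of the original spectrum
  if (drop_dc) ps <- ps[-1L]
  mu <- mean(ps)
  if (mu == 0) stop("degenerate all-zero spectrum: ratio statistics undefined")
  n <- length(ps)
  m2 <- mean((ps - mu)^2)
  sd_pop <- sqrt(m2)
  q <- stats::quantile(ps, c(0.15, 0.25, 0.50, 0.75), names = FALSE, type = 7)
  iqr <- q[4] - q[2]
  skew <- if (m2 > 0) mean((ps - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((ps - mu)^4) / m2^2 else 0
  c(papr = max(ps) / mu,
    snr = snr_bin / mu,
    min = min(ps), max = max(ps), median = q[3],
    sd_pop = sd_pop, sd_samp = stats::sd(ps),
    p15 = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
    var = stats::var(ps),
    cv = sd_pop / mu,
    amplitude = max(ps) - min(ps),
    semi_iqr = iqr / 2, iqr = iqr,
    skewness = skew, kurtosis = kurt)
}

#' Fused spectral feature vector (RFF) of one sequence
#'
#' Concatenates the 18 spectral descriptors of the power spectrum of each of
#' the five encodings, in the fixed order binary, integer, real, zcurve, eiip:
#' 5 x 18 = 90 named features (`<scheme>_<stat>`).
#'
#' @param residues an A/C/G/T string of length >= 2.
#' @return named numeric vector of length 90.
#' @export
rff_vector <- function(residues) {
  out <- unlist(lapply(.SCHEMES, function(sch) {
    spectral_descriptors(power_spectrum(encode_sequence(residues, sch)))
  }))
  names(out) <- as.vector(outer(.DESCRIPTOR_NAMES, .SCHEMES,
                                function(s, sch) paste(sch, s, sep = "_")))
  out
}

#' RFF feature matrix for a dataset
#'
#' @param ds a [fasta_dataset()] (sanitized; every sequence length >= 2).
#' @return numeric matrix, one row per record (rownames = ids), 90 columns.
#' @export
rff_features <- function(ds) {
  stopifnot(inherits(ds, "fasta_dataset"))
  m <- t(vapply(ds$residues, rff_vector, numeric(90), USE.NAMES = FALSE))
  rownames(m) <- ds$id
  m
}
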
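#' Position weight matrix
#'
#' A per-position, per-base additive score table used to detect binding
#' motifs of SR proteins. A window's score is the sum over positions of the
#' score of the base observed at that position.
#'
#' @param name Matrix name.
#' @param matrix Numeric matrix, one row per motif position, columns in
#'   fixed A, C, G, T order.
#' @param threshold Either an absolute score cutoff (`threshold_type =
#'   "absolute"`) or a fraction of the score range (`threshold_type =
#'   "fraction"`), resolved by [pwm_cutoff()].
#' @param threshold_type `"fraction"` (default) or `"absolute"`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, matrix, threshold = 0.9,
                threshold_type = c("fraction", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1) abort("PWM must have width >= 1")
  if (ncol(matrix) != 4) abort("PWM must have 4 columns (A,C,G,T)")
  if (!all(is.finite(matrix))) abort("PWM cells must all be finite")
  colnames(matrix) <- BASES
  if (threshold_type == "fraction" && (threshold < 0 || threshold > 1)) {
    abort("fractional threshold must lie in [0, 1]")
  }
  structure(
    list(name = name, matrix = matrix, threshold = threshold,
         threshold_type = threshold_type),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s  width=%d  threshold=%g (%s)\n",
    x$name, nrow(x$matrix), x$threshold, x$threshold_type
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Resolve a PWM's scanning cutoff
#'
#' Fractional thresholds are interpreted relative to the matrix score range:
#' `cutoff = min_score + frac * (max_score - min_score)`, where min/max are
#' the sums of per-position minima/maxima. Absolute thresholds are returned
#' unchanged.
#'
#' @param pwm A [pwm()] object.
#' @return The absolute score cutoff.
#' @export
pwm_cutoff <- function(pwm) {
  if (pwm$threshold_type == "absolute") return(pwm$threshold)
  mx <- sum(apply(pwm$matrix, 1, max))
  mn <- sum(apply(pwm$matrix, 1, min))
  mn + pwm$threshold * (mx - mn)
}

#' Score one window against a PWM
#'
#' @param pwm A [pwm()] object.
#' @param window A string of length `nrow(pwm$matrix)` over `{A,C,G,T}`.
#' @return The additive score.
#' @export
pwm_score <- function(pwm, window) {
  w <- nrow(pwm$matrix)
  if (nchar(window) != w) {
    abort(sprintf("window length %d != PWM width %d", nchar(window), w))
  }
  idx <- match(chars(window), BASES)
  if (anyNA(idx)) {
    abort(paste0("window contains a non-ACGT character: ", window))
  }
  sum(pwm$matrix[cbind(seq_len(w), idx)])
}

#' Scan a sequence with a PWM
#'
#' Slides the matrix along the sense strand and reports every window whose
#' score reaches the resolved cutoff. Windows containing non-ACGT
#' characters (ambiguity codes, gaps) are skipped. Coordinates are 0-based
#' half-open.
#'
#' @param seq Nucleotide string.
#' @param pwm A [pwm()] object.
#' @param seq_id Identifier copied into the hits.
#' @return A tibble of hits: `seq_id`, `start`, `end`, `motif_name`,
#'   `score`, `kind` (`"ESE_PWM"`), `set_name`, sorted by `start`.
#' @export
scan_pwm <- function(seq, pwm, seq_id = "seq") {
  w <- nrow(pwm$matrix)
  n <- nchar(seq)
  if (n < w) return(empty_hits())
  idx <- match(chars(toupper(seq)), BASES)
  cutoff <- pwm_cutoff(pwm)
  nwin <- n - w + 1L
  sc <- rep(0, nwin)
  ok <- rep(TRUE, nwin)
  for (p in seq_len(w)) {
    b <- idx[p:(p + nwin - 1L)]
    ok <- ok & !is.na(b)
    col <- pwm$matrix[p, ]
    sc <- sc + ifelse(is.na(b), 0, col[b])
  }
  keep <- which(ok & sc >= cutoff)
  tibble(
    seq_id = rep(seq_id, length(keep)),
    start = keep - 1L,
    end = keep - 1L + w,
    motif_name = rep(pwm$name, length(keep)),
    score = sc[keep],
    kind = rep("ESE_PWM", length(keep)),
    set_name = rep(pwm$name, length(keep))
  )
}

empty_hits <- function() {
  tibble(
    seq_id = character(0), start = integer(0), end = integer(0),
    motif_name = character(0), score = numeric(0), kind = character(0),
    set_name = character(0)
  )
}

#' Hexamer motif set
#'
#' A set of 6-mers scanned by presence/absence, optionally carrying
#' per-member log-odds scores (used for silencer sets scored by their
#' frequency contrast between pseudoexons and exons).
#'
#' @param name Set name.
#' @param members Character vector of unique 6-letter strings over
#'   `{A,C,G,T}`.
#' @param scores Optional named numeric vector of member scores.
#' @param kind `"ESE_HEX"` (enhancer set) or `"ESS_HEX"` (silencer set).
#' @return An object of class `hexamer_set`.
#' @export
hexamer_set <- function(name, members, scores = NULL,
                        kind = c("ESE_HEX", "ESS_HEX")) {
  kind <- match.arg(kind)
  members <- toupper(members)
  if (any(nchar(members) != 6)) abort("all hexamer members must have length 6")
  if (any(!grepl("^[ACGT]{6}$", members))) {
    abort("hexamer members must be over {A,C,G,T}")
  }
  if (anyDuplicated(members)) abort("hexamer members must be unique")
  if (!is.null(scores)) {
    scores <- scores[members]
    names(scores) <- members
  }
  structure(
    list(name = name, members = members, scores = scores, kind = kind),
    class = "hexamer_set"
  )
}

#' @export
print.hexamer_set <- function(x, ...) {
  cat(sprintf(
    "<hexamer_set> %s  %d members  kind=%s  %s\n",
    x$name, length(x$members), x$kind,
    if (is.null(x$scores)) "unscored" else "scored"
  ))
  invisible(x)
}

#' Scan a sequence for hexamer-set occurrences
#'
#' Every occurrence of every member is reported; overlapping occurrences are
#' all kept. The hit score is the member's set score if the set is scored,
#' else 0.
#'
#' @param seq Nucleotide string.
#' @param hexset A [hexamer_set()] object.
#' @param seq_id Identifier copied into the hits.
#' @return A tibble of hits like [scan_pwm()], with `kind` from the set.
#' @export
scan_hexamers <- function(seq, hexset, seq_id = "seq") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) return(empty_hits())
  wins <- substring(seq, 1:(n - 5), 6:n)
  hit <- which(wins %in% hexset$members)
  motifs <- wins[hit]
  sc <- if (is.null(hexset$scores)) {
    rep(0, length(hit))
  } else {
    unname(hexset$scores[motifs])
  }
  tibble(
    seq_id = rep(seq_id, length(hit)),
    start = hit - 1L,
    end = hit + 5L,
    motif_name = motifs,
    score = sc,
    kind = rep(hexset$kind, length(hit)),
    set_name = rep(hexset$name, length(hit))
  ) |> arrange(.data$start)
}

#' Silencer log-odds score
#'
#' Log2 ratio of a hexamer's frequency in pseudoexons versus real exons;
#' positive values mark silencer-like enrichment in pseudoexons.
#'
#' @param freq_pseudoexon,freq_exon Frequencies, both strictly positive.
#' @return `log2(freq_pseudoexon / freq_exon)`.
#' @export
ess_logodds <- function(freq_pseudoexon, freq_exon) {
  if (any(freq_pseudoexon <= 0) || any(freq_exon <= 0)) {
    abort("frequencies must be strictly positive")
  }
  log2(freq_pseudoexon / freq_exon)
}

#' Scan one sequence with several motif sets
#'
#' Convenience wrapper binding the hits of [scan_pwm()] and
#' [scan_hexamers()] over lists of motif sets.
#'
#' @param seq Nucleotide string.
#' @param pwms List of [pwm()] objects.
#' @param hexsets List of [hexamer_set()] objects.
#' @param seq_id Identifier copied into the hits.
#' @return A tibble of hits sorted by `start`.
#' @export
scan_motifs <- function(seq, pwms = list(), hexsets = list(),
                        seq_id = "seq") {
  hits <- c(
    list(empty_hits()),
    lapply(pwms, function(p) scan_pwm(seq, p, seq_id = seq_id)),
    lapply(hexsets, function(h) scan_hexamers(seq, h, seq_id = seq_id))
  )
  bind_rows(hits) |> arrange(.data$start)
}
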
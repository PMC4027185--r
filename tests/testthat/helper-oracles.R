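# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles deliberately re-derive results by direct enumeration, never by
# calling the code paths they check.

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
.BASES <- c("A", "C", "G", "T")

# --- motif oracles ---------------------------------------------------------

# per-window table-lookup sum over every full window, plain loops
oracle_scan_pwm <- function(seq, mat, cutoff) {
  w <- nrow(mat)
  s <- .chars(seq)
  out <- list()
  if (length(s) < w) return(data.frame(start = integer(0), score = numeric(0)))
  for (st in 0:(length(s) - w)) {
    win <- s[(st + 1):(st + w)]
    idx <- match(win, .BASES)
    if (anyNA(idx)) next
    sc <- 0
    for (p in seq_len(w)) sc <- sc + mat[p, idx[p]]
    if (sc >= cutoff) out[[length(out) + 1]] <- c(st, sc)
  }
  if (!length(out)) return(data.frame(start = integer(0), score = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), score = m[, 2])
}

# naive O(n*m) substring scan
oracle_scan_hex <- function(seq, members) {
  out <- list()
  n <- nchar(seq)
  for (h in members) {
    if (n < 6) next
    for (st in 0:(n - 6)) {
      if (substr(seq, st + 1, st + 6) == h) {
        out[[length(out) + 1]] <- data.frame(start = st, motif = h)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), motif = character(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$motif), , drop = FALSE]
}

random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

random_pwm_matrix <- function(w) {
  matrix(round(rnorm(w * 4), 3), nrow = w,
         dimnames = list(NULL, .BASES))
}

# --- alignment oracle ------------------------------------------------------

# exhaustive-recursion affine-gap global alignment score; gap of length L
# costs open + L * ext (first gapped position charged open + ext)
oracle_align_score <- function(a, b, sub, open = 10, ext = 0.5) {
  A <- .chars(a)
  B <- .chars(b)
  n <- length(A)
  m <- length(B)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, st) {
    key <- paste(i, j, st)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == 0 && j == 0) {
      if (st == "M") 0 else -Inf
    } else if (st == "M") {
      if (i == 0 || j == 0) -Inf else {
        sub[A[i], B[j]] +
          max(f(i - 1, j - 1, "M"), f(i - 1, j - 1, "X"), f(i - 1, j - 1, "Y"))
      }
    } else if (st == "X") {      # A residue against a gap
      if (i == 0) -Inf else {
        max(f(i - 1, j, "M") - open - ext,
            f(i - 1, j, "X") - ext,
            f(i - 1, j, "Y") - open - ext)
      }
    } else {                     # B residue against a gap
      if (j == 0) -Inf else {
        max(f(i, j - 1, "M") - open - ext,
            f(i, j - 1, "X") - open - ext,
            f(i, j - 1, "Y") - ext)
      }
    }
    memo[[key]] <- val
    val
  }
  max(f(n, m, "M"), f(n, m, "X"), f(n, m, "Y"))
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# random exon record encoding n_res random residues (sense codons, no stop)
random_exon_record <- function(id, n_res) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  exon_record(id, paste(sample(sense, n_res, replace = TRUE), collapse = ""))
}

# --- maximum-entropy oracles -----------------------------------------------

# closed-form weight-matrix log-odds computed directly from raw counts
oracle_wmm_score <- function(windows, window, pc = 0.5) {
  w <- nchar(windows[1])
  n <- length(windows)
  sc <- 0
  for (p in seq_len(w)) {
    col <- substr(windows, p, p)
    b <- substr(window, p, p)
    prob <- (sum(col == b) + pc) / (n + 4 * pc)
    sc <- sc + log2(prob) - log2(0.25)
  }
  sc
}

all_windows_chr <- function(w) {
  grid <- expand.grid(rep(list(.BASES), w), stringsAsFactors = FALSE)
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# empirical plug-in entropy (bits) of a window sample
empirical_entropy <- function(windows) {
  p <- table(windows) / length(windows)
  -sum(p * log2(p))
}

# --- shared splice models (trained once per test run) ----------------------

.model_cache <- new.env(parent = emptyenv())

ss_test_models <- function() {
  if (is.null(.model_cache$models)) {
    .model_cache$models <- list(
      acceptor = default_site_model("acceptor", n_train = 1500L, seed = 101L),
      donor = default_site_model("donor", n_train = 1500L, seed = 102L)
    )
  }
  .model_cache$models
}

plant_hexset <- function() hexamer_set("plant", "GAAGAA")

plant_config <- function() {
  screen_config(ese_hexsets = list(plant_hexset()),
                site_of_interest = "acceptor")
}
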
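#' Splice-site window specification
#'
#' Fixed windows straddling an exon/intron boundary. Defaults follow the
#' maximum-entropy splice-model convention: donor windows carry 3 exonic +
#' 6 intronic nucleotides (width 9), acceptor windows 20 intronic + 3
#' exonic nucleotides (width 23).
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @param exonic_len,intronic_len Window composition in nucleotides;
#'   defaults depend on `site_type`.
#' @return An object of class `site_window_spec` with fields `site_type`,
#'   `exonic_len`, `intronic_len`, `width`.
#' @export
site_window_spec <- function(site_type = c("donor", "acceptor"),
                             exonic_len = NULL, intronic_len = NULL) {
  site_type <- match.arg(site_type)
  if (is.null(exonic_len)) exonic_len <- 3L
  if (is.null(intronic_len)) {
    intronic_len <- if (site_type == "donor") 6L else 20L
  }
  if (exonic_len < 0 || intronic_len < 0 || exonic_len + intronic_len < 1) {
    abort("window lengths must be non-negative with positive total width")
  }
  structure(
    list(site_type = site_type, exonic_len = as.integer(exonic_len),
         intronic_len = as.integer(intronic_len),
         width = as.integer(exonic_len + intronic_len)),
    class = "site_window_spec"
  )
}

#' Extract the splice-site window from an exon with flanks
#'
#' Acceptor windows are the last `intronic_len` nt of the upstream intron
#' followed by the first `exonic_len` nt of the exon; donor windows are the
#' last `exonic_len` nt of the exon followed by the first `intronic_len` nt
#' of the downstream intron.
#'
#' @param exon_seq Exon nucleotide string.
#' @param upstream_flank,downstream_flank Flanking intron sequence (only the
#'   relevant side must be long enough).
#' @param site_type `"donor"` or `"acceptor"`.
#' @param spec A [site_window_spec()]; defaults to the convention for
#'   `site_type`.
#' @return The window string of width `spec$width`.
#' @export
extract_site_window <- function(exon_seq, upstream_flank = "",
                                downstream_flank = "",
                                site_type = c("donor", "acceptor"),
                                spec = NULL) {
  site_type <- match.arg(site_type)
  spec <- spec %||% site_window_spec(site_type)
  if (spec$site_type != site_type) {
    abort("spec$site_type does not match site_type")
  }
  el <- spec$exonic_len
  il <- spec$intronic_len
  if (nchar(exon_seq) < el) {
    abort(sprintf("exon too short: need %d exonic nt, have %d",
                  el, nchar(exon_seq)))
  }
  if (site_type == "acceptor") {
    if (nchar(upstream_flank) < il) {
      abort(sprintf(
        "flank too short for acceptor window: need %d intronic nt, have %d (deficit %d)",
        il, nchar(upstream_flank), il - nchar(upstream_flank)
      ))
    }
    paste0(
      str_sub(upstream_flank, nchar(upstream_flank) - il + 1L),
      str_sub(exon_seq, 1L, el)
    )
  } else {
    if (nchar(downstream_flank) < il) {
      abort(sprintf(
        "flank too short for donor window: need %d intronic nt, have %d (deficit %d)",
        il, nchar(downstream_flank), il - nchar(downstream_flank)
      ))
    }
    paste0(
      str_sub(exon_seq, nchar(exon_seq) - el + 1L),
      str_sub(downstream_flank, 1L, il)
    )
  }
}

# ---------------------------------------------------------------------------
# Factored categorical distributions over fixed-width ACGT windows.
#
# Three representations:
#  * "singleton": width x 4 matrix of per-position base probabilities
#    (independence model; the classical weight matrix).
#  * "chain": per-position marginals plus adjacent-pair tables; the
#    maximum-entropy distribution under singleton + adjacent-pair
#    constraints factorises exactly as
#       P(x) = P1(x1) * prod_i P(x_{i+1} | x_i)
#    so normalisation is exact at any width (no full table needed).
#  * "table": full 4^width probability table fitted by iterative
#    proportional fitting for arbitrary constraint subsets (width <= 9).
# ---------------------------------------------------------------------------

dist_singleton <- function(marg) {
  structure(list(kind = "singleton", marg = marg), class = "window_dist")
}

dist_chain <- function(marg, pairs) {
  structure(list(kind = "chain", marg = marg, pairs = pairs),
            class = "window_dist")
}

dist_table <- function(table, width) {
  structure(list(kind = "table", table = table, width = width),
            class = "window_dist")
}

dist_uniform <- function(width) {
  marg <- matrix(0.25, nrow = width, ncol = 4, dimnames = list(NULL, BASES))
  dist_singleton(marg)
}

dist_width <- function(d) {
  switch(d$kind,
    singleton = nrow(d$marg),
    chain = nrow(d$marg),
    table = d$width
  )
}

# log2-probability of one window (character indices 1..4)
dist_logp <- function(d, idx) {
  w <- length(idx)
  switch(d$kind,
    singleton = sum(log2(d$marg[cbind(seq_len(w), idx)])),
    chain = {
      lp <- log2(d$marg[1, idx[1]])
      for (i in seq_len(w - 1L)) {
        lp <- lp + log2(d$pairs[[i]][idx[i], idx[i + 1L]]) -
          log2(d$marg[i, idx[i]])
      }
      unname(lp)
    },
    table = log2(d$table[window_index(idx)])
  )
}

# linear index of a window in the flattened 4^w table (position 1 fastest)
window_index <- function(idx) {
  sum((idx - 1L) * 4L^(seq_along(idx) - 1L)) + 1L
}

# all 4^w windows as an integer matrix (rows = windows), w small
all_windows <- function(w) {
  as.matrix(expand.grid(rep(list(1:4), w)))
}

windows_to_idx <- function(windows, width) {
  mat <- matrix(match(unlist(strsplit(toupper(windows), "")), BASES),
                ncol = width, byrow = TRUE)
  if (anyNA(mat)) abort("training windows must be over {A,C,G,T}")
  mat
}

# empirical singleton marginals with pseudocount pc per cell
empirical_marg <- function(idx_mat, pc) {
  w <- ncol(idx_mat)
  n <- nrow(idx_mat)
  marg <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, BASES))
  for (p in seq_len(w)) {
    cnt <- tabulate(idx_mat[, p], nbins = 4)
    marg[p, ] <- (cnt + pc) / (n + 4 * pc)
  }
  marg
}

# empirical adjacent-pair tables with pseudocount pc per pair cell; the
# implied per-position marginals are consistent between neighbouring pairs
# because the pseudocount mass is uniform.
empirical_pairs <- function(idx_mat, pc) {
  w <- ncol(idx_mat)
  n <- nrow(idx_mat)
  lapply(seq_len(w - 1L), function(i) {
    tab <- matrix(pc, 4, 4, dimnames = list(BASES, BASES))
    for (r in seq_len(n)) {
      tab[idx_mat[r, i], idx_mat[r, i + 1L]] <-
        tab[idx_mat[r, i], idx_mat[r, i + 1L]] + 1
    }
    tab / (n + 16 * pc)
  })
}

# marginals implied by pair tables (consistent chain construction)
pairs_to_marg <- function(pairs) {
  w <- length(pairs) + 1L
  marg <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, BASES))
  marg[1, ] <- rowSums(pairs[[1]])
  for (i in seq_len(w - 1L)) marg[i + 1L, ] <- colSums(pairs[[i]])
  marg
}

# iterative proportional fitting of the full 4^w table to the empirical
# marginals on arbitrary position subsets
ipf_fit <- function(idx_mat, subsets, pc, tol, max_iter) {
  w <- ncol(idx_mat)
  if (w > 9) abort("full-table fitting is limited to width <= 9")
  n <- nrow(idx_mat)
  grid <- all_windows(w)
  # empirical marginal table for each subset, flattened by subset index
  subset_key <- function(mat, s) {
    k <- mat[, s[1]]
    if (length(s) > 1) {
      for (j in 2:length(s)) k <- k + (mat[, s[j]] - 1L) * 4L^(j - 1L)
    }
    k
  }
  # all targets are marginals of ONE smoothed joint (counts plus a uniform
  # pseudo-mass of alpha), so constraints of different sizes are mutually
  # consistent and the chain/singleton closed forms are exact special cases
  alpha <- pc * 4^max(vapply(subsets, length, integer(1)))
  targets <- lapply(subsets, function(s) {
    cells <- 4L^length(s)
    cnt <- tabulate(subset_key(idx_mat, s), nbins = cells)
    (cnt + alpha / cells) / (n + alpha)
  })
  keys <- lapply(subsets, function(s) subset_key(grid, s))
  tab <- rep(1 / 4^w, 4^w)
  iter <- 0L
  disc <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    disc <- 0
    for (k in seq_along(subsets)) {
      cur <- as.vector(rowsum(tab, keys[[k]]))
      disc <- max(disc, max(abs(cur - targets[[k]])))
      ratio <- targets[[k]] / cur
      tab <- tab * ratio[keys[[k]]]
    }
    # re-check after the sweep
    post <- max(vapply(seq_along(subsets), function(k) {
      max(abs(as.vector(rowsum(tab, keys[[k]])) - targets[[k]]))
    }, numeric(1)))
    if (post < tol) {
      disc <- post
      break
    }
    disc <- post
  }
  list(table = tab / sum(tab), iterations = iter, discrepancy = disc,
       converged = disc < tol)
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the highest-entropy distribution over fixed-width windows whose
#' marginals on the chosen position subsets match the empirical marginals
#' of the training windows, and an analogous background distribution. With
#' singleton constraints the solution is the product of per-position base
#' frequencies (the classical weight matrix); with singleton plus
#' adjacent-pair constraints it factorises exactly as a first-order chain.
#' Arbitrary subsets are fitted on the full table by iterative proportional
#' fitting (width <= 9 only).
#'
#' @param site_windows Character vector of signal training windows, all of
#'   width `spec$width`, over `{A,C,G,T}`.
#' @param background_windows Optional background training windows; when
#'   `NULL` the background is uniform over bases.
#' @param spec A [site_window_spec()].
#' @param constraints `"chain"` (default: singletons + adjacent pairs),
#'   `"singleton"`, or a list of integer position subsets.
#' @param pseudocount Pseudocount added per contingency cell (default 0.5).
#' @param tol Convergence tolerance on marginal discrepancy (IPF only).
#' @param max_iter Maximum IPF sweeps.
#' @return An object of class `splice_model`.
#' @export
train_maxent <- function(site_windows, background_windows = NULL, spec,
                         constraints = "chain", pseudocount = 0.5,
                         tol = 1e-8, max_iter = 200L) {
  if (length(site_windows) < 1) abort("need at least one training window")
  w <- spec$width
  if (any(nchar(site_windows) != w)) {
    abort(sprintf("all signal windows must have width %d", w))
  }
  fit_one <- function(windows) {
    idx_mat <- windows_to_idx(windows, w)
    if (identical(constraints, "singleton")) {
      list(dist = dist_singleton(empirical_marg(idx_mat, pseudocount)),
           iterations = 0L, discrepancy = 0, converged = TRUE,
           method = "closed-form singleton")
    } else if (identical(constraints, "chain")) {
      if (w == 1L) {
        list(dist = dist_singleton(empirical_marg(idx_mat, pseudocount)),
             iterations = 0L, discrepancy = 0, converged = TRUE,
             method = "closed-form singleton")
      } else {
        pairs <- empirical_pairs(idx_mat, pseudocount)
        list(dist = dist_chain(pairs_to_marg(pairs), pairs),
             iterations = 0L, discrepancy = 0, converged = TRUE,
             method = "closed-form chain")
      }
    } else if (is.list(constraints)) {
      subsets <- lapply(constraints, as.integer)
      if (any(vapply(subsets, function(s) any(s < 1 | s > w), logical(1)))) {
        abort("constraint positions must lie in 1..width")
      }
      res <- ipf_fit(windows_to_idx(windows, w), subsets, pseudocount,
                     tol, max_iter)
      if (!res$converged) {
        warn(sprintf(
          "IPF did not converge (discrepancy %.3g after %d sweeps)",
          res$discrepancy, res$iterations
        ))
      }
      list(dist = dist_table(res$table, w), iterations = res$iterations,
           discrepancy = res$discrepancy, converged = res$converged,
           method = "IPF full table")
    } else {
      abort("constraints must be \"singleton\", \"chain\" or a list of subsets")
    }
  }
  sig <- fit_one(site_windows)
  if (is.null(background_windows)) {
    bg <- list(dist = dist_uniform(w), iterations = 0L, discrepancy = 0,
               converged = TRUE, method = "uniform background")
    n_bg <- 0L
  } else {
    if (any(nchar(background_windows) != w)) {
      abort(sprintf("all background windows must have width %d", w))
    }
    bg <- fit_one(background_windows)
    n_bg <- length(background_windows)
  }
  structure(
    list(
      spec = spec,
      constraints = constraints,
      signal = sig$dist,
      background = bg$dist,
      pseudocount = pseudocount,
      fit = list(
        method = sig$method,
        iterations = sig$iterations,
        tol = tol,
        discrepancy = max(sig$discrepancy, bg$discrepancy),
        converged = sig$converged && bg$converged,
        n_signal = length(site_windows),
        n_background = n_bg
      )
    ),
    class = "splice_model"
  )
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf(
    "<splice_model> %s  width=%d (%d exonic + %d intronic)\n",
    x$spec$site_type, x$spec$width, x$spec$exonic_len, x$spec$intronic_len
  ))
  cat(sprintf(
    "  fit: %s, n_signal=%d, converged=%s\n",
    x$fit$method, x$fit$n_signal, x$fit$converged
  ))
  invisible(x)
}

#' Score a window under a splice-site model
#'
#' Returns the log2 odds of the window under the signal versus background
#' distribution, in bits. Pseudocounts applied at training time guarantee
#' both probabilities are positive.
#'
#' @param model A [train_maxent()] model.
#' @param window Window string of the model's width over `{A,C,G,T}`.
#' @return Score in bits.
#' @export
score_site <- function(model, window) {
  w <- model$spec$width
  if (nchar(window) != w) {
    abort(sprintf("window length %d != model width %d", nchar(window), w))
  }
  idx <- match(chars(toupper(window)), BASES)
  if (anyNA(idx)) abort(paste0("window contains non-ACGT character: ", window))
  dist_logp(model$signal, idx) - dist_logp(model$background, idx)
}

#' Score many windows under a splice-site model
#'
#' @param model A [train_maxent()] model.
#' @param windows Character vector of windows.
#' @return A tibble with columns `window` and `score`.
#' @export
score_sites <- function(model, windows) {
  tibble(
    window = windows,
    score = vapply(windows, function(x) score_site(model, x), numeric(1),
                   USE.NAMES = FALSE)
  )
}

#' Classify splice-site strength
#'
#' @param score Score in bits.
#' @param cutoffs Numeric length-2 vector `c(weak_below, strong_at_or_above)`.
#' @return A tibble with columns `score`, `label` (`weak`, `intermediate`,
#'   `strong`), `weak_below`, `strong_at_or_above`.
#' @export
classify_strength <- function(score, cutoffs = c(3, 6)) {
  if (length(cutoffs) != 2 || cutoffs[1] > cutoffs[2]) {
    abort("cutoffs must be c(weak_below, strong_at_or_above) with weak_below <= strong_at_or_above")
  }
  label <- ifelse(score < cutoffs[1], "weak",
                  ifelse(score >= cutoffs[2], "strong", "intermediate"))
  tibble(
    score = score, label = label,
    weak_below = cutoffs[1], strong_at_or_above = cutoffs[2]
  )
}

# exact entropy in bits; exhaustive for table, closed form for factored
dist_entropy <- function(d) {
  w <- dist_width(d)
  switch(d$kind,
    singleton = -sum(vapply(seq_len(w), function(p) {
      pr <- d$marg[p, ]
      sum(pr * log2(pr))
    }, numeric(1))),
    chain = {
      hp <- -sum(vapply(d$pairs, function(tab) sum(tab * log2(tab)),
                        numeric(1)))
      hs <- if (w > 2) {
        -sum(vapply(2:(w - 1L), function(p) {
          pr <- d$marg[p, ]
          sum(pr * log2(pr))
        }, numeric(1)))
      } else 0
      hp - hs
    },
    table = {
      pr <- d$table[d$table > 0]
      -sum(pr * log2(pr))
    }
  )
}

#' Entropy of a fitted splice-model distribution
#'
#' @param model A [train_maxent()] model.
#' @param which `"signal"` or `"background"`.
#' @return Entropy in bits.
#' @export
model_entropy <- function(model, which = c("signal", "background")) {
  which <- match.arg(which)
  dist_entropy(model[[which]])
}

# sample n windows from a distribution; forward sampling for chains
dist_sample <- function(d, n) {
  w <- dist_width(d)
  out <- matrix(0L, nrow = n, ncol = w)
  switch(d$kind,
    singleton = {
      for (p in seq_len(w)) {
        out[, p] <- sample.int(4, n, replace = TRUE, prob = d$marg[p, ])
      }
    },
    chain = {
      out[, 1] <- sample.int(4, n, replace = TRUE, prob = d$marg[1, ])
      for (i in seq_len(w - 1L)) {
        cond <- d$pairs[[i]] / rowSums(d$pairs[[i]])
        for (b in 1:4) {
          rows <- which(out[, i] == b)
          if (length(rows)) {
            out[rows, i + 1L] <- sample.int(4, length(rows), replace = TRUE,
                                            prob = cond[b, ])
          }
        }
      }
    },
    table = {
      pick <- sample.int(length(d$table), n, replace = TRUE, prob = d$table)
      grid <- all_windows(w)
      out <- grid[pick, , drop = FALSE]
    }
  )
  apply(out, 1, function(r) paste(BASES[r], collapse = ""))
}

#' Write a splice-site model to a self-describing JSON file
#'
#' Numbers are serialised at full precision so read/write round-trips are
#' exact.
#'
#' @param model A [train_maxent()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_model <- function(model, path) {
  ser_dist <- function(d) {
    switch(d$kind,
      singleton = list(kind = "singleton", marg = d$marg),
      chain = list(kind = "chain", marg = d$marg, pairs = d$pairs),
      table = list(kind = "table", width = d$width, table = d$table)
    )
  }
  obj <- list(
    format = "splicescreen-model-1",
    spec = model$spec[c("site_type", "exonic_len", "intronic_len")],
    constraints = model$constraints,
    pseudocount = model$pseudocount,
    fit = model$fit,
    signal = ser_dist(model$signal),
    background = ser_dist(model$background)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a splice-site model written by [write_splice_model()]
#'
#' @param path Path to the model file.
#' @return A `splice_model` object.
#' @export
read_splice_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "splicescreen-model-1")) {
    abort(paste0("not a splicescreen model file: ", path))
  }
  de_dist <- function(d) {
    if (d$kind == "singleton") {
      m <- as.matrix(d$marg)
      colnames(m) <- BASES
      dist_singleton(m)
    } else if (d$kind == "chain") {
      m <- as.matrix(d$marg)
      colnames(m) <- BASES
      pairs <- if (is.array(d$pairs) && length(dim(d$pairs)) == 3) {
        lapply(seq_len(dim(d$pairs)[1]), function(i) {
          tab <- d$pairs[i, , ]
          dimnames(tab) <- list(BASES, BASES)
          tab
        })
      } else {
        lapply(d$pairs, function(tab) {
          tab <- as.matrix(tab)
          dimnames(tab) <- list(BASES, BASES)
          tab
        })
      }
      dist_chain(m, pairs)
    } else {
      dist_table(as.numeric(d$table), as.integer(d$width))
    }
  }
  spec <- site_window_spec(obj$spec$site_type, obj$spec$exonic_len,
                           obj$spec$intronic_len)
  constraints <- obj$constraints
  if (is.list(constraints)) constraints <- lapply(constraints, as.integer)
  structure(
    list(
      spec = spec, constraints = constraints,
      signal = de_dist(obj$signal), background = de_dist(obj$background),
      pseudocount = obj$pseudocount,
      fit = as.list(obj$fit)
    ),
    class = "splice_model"
  )
}

#' @export
tidy.splice_model <- function(x, ...) {
  marg <- if (x$signal$kind %in% c("singleton", "chain")) {
    x$signal$marg
  } else {
    # marginalise the full table
    w <- x$signal$width
    grid <- all_windows(w)
    m <- matrix(0, w, 4, dimnames = list(NULL, BASES))
    for (p in seq_len(w)) {
      m[p, ] <- as.vector(rowsum(x$signal$table, grid[, p]))
    }
    m
  }
  as_tibble(as.data.frame(marg)) |>
    mutate(position = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "base",
                        values_to = "probability")
}

#' @export
glance.splice_model <- function(x, ...) {
  tibble(
    site_type = x$spec$site_type,
    width = x$spec$width,
    method = x$fit$method,
    n_signal = x$fit$n_signal,
    n_background = x$fit$n_background,
    iterations = x$fit$iterations,
    discrepancy = x$fit$discrepancy,
    converged = x$fit$converged,
    signal_entropy = model_entropy(x, "signal")
  )
}

#' @export
autoplot.splice_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(
      title = sprintf("%s site model (signal marginals)",
                      object$spec$site_type),
      x = "window position", y = NULL
    ) +
    ggplot2::theme_minimal()
}
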
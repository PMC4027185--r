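#' Screen configuration
#'
#' Parameters of the candidate screen: a paralog pair is flagged when one
#' member has a weak splice site, the other a strong one with at least
#' `min_delta` bits of contrast, the weak member carries enhancer motifs at
#' aligned positions where the strong member has none from the same motif
#' set, and the motif span carries (or is within `adjacency_window` codons
#' of) a non-synonymous difference.
#'
#' @param strength_cutoffs `c(weak_below, strong_at_or_above)` in bits.
#' @param min_delta Minimum strength contrast in bits (>= 0).
#' @param adjacency_window Codons an amino-acid difference may sit from an
#'   enhancer span and still count (default 1).
#' @param pwms,ese_hexsets Enhancer motif sets used for the screen.
#' @param ess_hexsets Silencer hexamer sets scanned for context only.
#' @param site_of_interest `"acceptor"`, `"donor"` or `"both"`.
#' @param column_mask Optional integer vector of protein-alignment columns
#'   to which candidate enhancer spans are restricted (e.g. an active-site
#'   region); `NULL` screens the whole exon.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(strength_cutoffs = c(3, 6), min_delta = 2,
                          adjacency_window = 1L, pwms = list(),
                          ese_hexsets = list(), ess_hexsets = list(),
                          site_of_interest = c("both", "acceptor", "donor"),
                          column_mask = NULL) {
  site_of_interest <- match.arg(site_of_interest)
  if (min_delta < 0) abort("min_delta must be >= 0")
  if (adjacency_window < 0) abort("adjacency_window must be >= 0")
  if (length(strength_cutoffs) != 2 ||
      strength_cutoffs[1] > strength_cutoffs[2]) {
    abort("strength_cutoffs must be c(weak_below, strong_at_or_above)")
  }
  structure(
    list(strength_cutoffs = strength_cutoffs, min_delta = min_delta,
         adjacency_window = as.integer(adjacency_window), pwms = pwms,
         ese_hexsets = ese_hexsets, ess_hexsets = ess_hexsets,
         site_of_interest = site_of_interest, column_mask = column_mask),
    class = "screen_config"
  )
}

#' Project motif hits onto alignment columns
#'
#' Converts exon-coordinate hits of one member into half-open
#' protein-column intervals of a codon alignment. Gap columns inside a
#' hit's span are retained in the interval.
#'
#' @param alignment A `codon_alignment`.
#' @param hits Hit tibble (0-based half-open exon coordinates).
#' @param member Member id the hits belong to.
#' @return The hits tibble with added `col_start`, `col_end` (1-based
#'   inclusive protein columns) and `nt_col_start`, `nt_col_end` (0-based
#'   half-open nucleotide columns).
#' @export
project_hits <- function(alignment, hits, member) {
  if (!member %in% alignment$members) abort(paste0("unknown member: ", member))
  phase <- alignment$phases[[member]]
  cmap <- alignment$column_map[[member]]
  n_codon <- sum(!is.na(cmap))
  # column of each source codon
  codon_col <- match(seq_len(n_codon), cmap)
  loc <- function(exon_pos0) {
    # exon position (0-based) -> source codon index, relative to the coding
    # region that the alignment covers
    rel <- exon_pos0 - phase
    if (rel < 0 || rel >= 3 * n_codon) {
      abort(sprintf(
        "hit at exon position %d lies outside the aligned coding region of %s",
        exon_pos0, member
      ))
    }
    rel %/% 3L + 1L
  }
  if (nrow(hits) == 0) {
    return(mutate(hits, col_start = integer(0), col_end = integer(0),
                  nt_col_start = integer(0), nt_col_end = integer(0)))
  }
  cs <- vapply(hits$start, function(s) codon_col[loc(s)], integer(1))
  ce <- vapply(hits$end - 1L, function(e) codon_col[loc(e)], integer(1))
  mutate(hits,
    col_start = cs, col_end = ce,
    nt_col_start = 3L * (cs - 1L) + (hits$start - phase) %% 3L,
    nt_col_end = 3L * (ce - 1L) + (hits$end - 1L - phase) %% 3L + 1L
  )
}

# strength of one record at one site type
site_strength <- function(rec, site_type, model, cutoffs) {
  win <- extract_site_window(
    rec$exon_seq, rec$upstream_flank, rec$downstream_flank,
    site_type = site_type, spec = model$spec
  )
  sc <- score_site(model, win)
  cl <- classify_strength(sc, cutoffs)
  list(score = sc, label = cl$label, window = win)
}

#' Screen one ordered paralog pair for splicing-constrained loci
#'
#' Tests both orientations of the pair: the putative weak member must
#' classify weak at the site of interest, the other strong, with a contrast
#' of at least `min_delta` bits; enhancer hits unique to the weak member at
#' aligned positions are intersected with nearby non-synonymous
#' differences. Silencer hits overlapping the retained enhancer spans are
#' attached as context.
#'
#' @param a,b [exon_record()] objects with flanks sufficient for the splice
#'   models' windows.
#' @param models Named list with elements `acceptor` and/or `donor`
#'   ([train_maxent()] models).
#' @param config A [screen_config()].
#' @return A tibble of candidate reports (possibly empty) with list-columns
#'   `ese_hits`, `diffs`, `ess_context`.
#' @export
screen_pair <- function(a, b, models, config) {
  sites <- switch(config$site_of_interest,
    both = c("acceptor", "donor"),
    config$site_of_interest
  )
  alignment <- align_pair(a, b)
  recs <- list(a, b)
  names(recs) <- c(a$seq_id, b$seq_id)
  ese_scan <- function(rec) {
    scan_motifs(rec$exon_seq, pwms = config$pwms,
                hexsets = config$ese_hexsets, seq_id = rec$seq_id)
  }
  ess_scan <- function(rec) {
    scan_motifs(rec$exon_seq, hexsets = config$ess_hexsets,
                seq_id = rec$seq_id)
  }
  # keep only hits fully inside the aligned coding region
  clip_hits <- function(hits, rec) {
    phase <- rec$phase
    n_codon <- sum(!is.na(alignment$column_map[[rec$seq_id]]))
    filter(hits, .data$start >= phase, .data$end <= phase + 3 * n_codon)
  }
  hits <- lapply(recs, function(r) clip_hits(ese_scan(r), r))
  ess_hits <- lapply(recs, function(r) clip_hits(ess_scan(r), r))
  out <- list()
  for (site in sites) {
    model <- models[[site]]
    if (is.null(model)) next
    strengths <- lapply(recs, site_strength, site_type = site, model = model,
                        cutoffs = config$strength_cutoffs)
    for (ori in list(c(1L, 2L), c(2L, 1L))) {
      weak <- recs[[ori[1]]]
      strong <- recs[[ori[2]]]
      s_weak <- strengths[[ori[1]]]
      s_strong <- strengths[[ori[2]]]
      if (s_weak$label != "weak" || s_strong$label != "strong") next
      if (s_strong$score - s_weak$score < config$min_delta) next
      hw <- project_hits(alignment, hits[[ori[1]]], weak$seq_id)
      hs <- project_hits(alignment, hits[[ori[2]]], strong$seq_id)
      if (!is.null(config$column_mask)) {
        hw <- filter(hw, .data$col_start %in% config$column_mask |
                       .data$col_end %in% config$column_mask)
      }
      if (nrow(hw) == 0) next
      # enhancer absence judged per motif set: any same-set hit of the
      # strong member overlapping the projected columns counts as present
      absent <- vapply(seq_len(nrow(hw)), function(k) {
        same <- filter(hs, .data$set_name == hw$set_name[k],
                       .data$col_start <= hw$col_end[k],
                       .data$col_end >= hw$col_start[k])
        nrow(same) == 0
      }, logical(1))
      hw <- hw[absent, ]
      if (nrow(hw) == 0) next
      diffs <- diff_columns(alignment, weak$seq_id, strong$seq_id) |>
        filter(.data$kind == "nonsynonymous")
      if (nrow(diffs) == 0) next
      aw <- config$adjacency_window
      near <- vapply(seq_len(nrow(hw)), function(k) {
        any(diffs$column >= hw$col_start[k] - aw &
              diffs$column <= hw$col_end[k] + aw)
      }, logical(1))
      hw <- hw[near, ]
      if (nrow(hw) == 0) next
      keep_diffs <- filter(diffs, vapply(.data$column, function(cc) {
        any(cc >= hw$col_start - aw & cc <= hw$col_end + aw)
      }, logical(1)))
      ess_near <- {
        he <- project_hits(alignment, ess_hits[[ori[1]]], weak$seq_id)
        filter(he, vapply(seq_len(nrow(he)), function(k) {
          any(he$col_start[k] <= hw$col_end & he$col_end[k] >= hw$col_start)
        }, logical(1)))
      }
      out[[length(out) + 1L]] <- tibble(
        weak_member = weak$seq_id,
        strong_member = strong$seq_id,
        site_type = site,
        strength_weak = s_weak$score,
        strength_strong = s_strong$score,
        delta = s_strong$score - s_weak$score,
        n_ese_hits = nrow(hw),
        n_diffs = nrow(keep_diffs),
        ese_hits = list(hw),
        diffs = list(keep_diffs),
        ess_context = list(ess_near),
        notes = if (nrow(ess_near) > 0) {
          "silencer hits overlap the enhancer span (context only)"
        } else ""
      )
    }
  }
  reports <- bind_rows(out)
  if (nrow(reports) == 0) empty_reports() else validate_reports(reports, config)
}

empty_reports <- function() {
  tibble(
    weak_member = character(0), strong_member = character(0),
    site_type = character(0), strength_weak = numeric(0),
    strength_strong = numeric(0), delta = numeric(0),
    n_ese_hits = integer(0), n_diffs = integer(0),
    ese_hits = list(), diffs = list(), ess_context = list(),
    notes = character(0)
  )
}

validate_reports <- function(reports, config) {
  stopifnot(
    all(reports$delta >= config$min_delta),
    all(reports$n_ese_hits >= 1),
    all(reports$n_diffs >= 1)
  )
  reports
}

#' Screen a paralog family
#'
#' Runs [screen_pair()] over every unordered pair of records (both
#' orientations are screened inside each pair) and deduplicates reports by
#' weak member, strong member, site type and enhancer spans.
#'
#' @param records List of [exon_record()] objects (>= 2).
#' @inheritParams screen_pair
#' @return A tibble of candidate reports.
#' @export
screen_family <- function(records, models, config) {
  if (length(records) < 2) abort("need at least 2 records to screen")
  pairs <- utils::combn(length(records), 2, simplify = FALSE)
  reports <- bind_rows(lapply(pairs, function(p) {
    screen_pair(records[[p[1]]], records[[p[2]]], models, config)
  }))
  if (nrow(reports) == 0) return(empty_reports())
  key <- vapply(seq_len(nrow(reports)), function(i) {
    spans <- reports$ese_hits[[i]]
    paste(
      reports$weak_member[i], reports$strong_member[i], reports$site_type[i],
      paste(spans$col_start, spans$col_end, sep = "-", collapse = ";")
    )
  }, character(1))
  reports[!duplicated(key), ]
}

#' Serialise candidate reports to a flat TSV-ready tibble
#'
#' Nested hit and difference tables are collapsed into `;`-joined span
#' strings with 1-based inclusive coordinates.
#'
#' @param reports Output of [screen_family()] or [screen_pair()].
#' @return A flat tibble with one row per report.
#' @export
flatten_reports <- function(reports) {
  if (nrow(reports) == 0) {
    return(select(reports, -"ese_hits", -"diffs", -"ess_context"))
  }
  mutate(
    reports,
    ese_spans = map_chr(.data$ese_hits, function(h) {
      paste(sprintf("%s:%d-%d", h$motif_name, h$start + 1L, h$end),
            collapse = ";")
    }),
    diff_list = map_chr(.data$diffs, function(d) {
      paste(sprintf("col%d:%s>%s", d$column, d$aa_i, d$aa_j), collapse = ";")
    }),
    ess_spans = map_chr(.data$ess_context, function(h) {
      if (nrow(h) == 0) "" else {
        paste(sprintf("%s:%d-%d", h$motif_name, h$start + 1L, h$end),
              collapse = ";")
      }
    })
  ) |>
    select(-"ese_hits", -"diffs", -"ess_context")
}

#' Render a human-readable annotated-alignment block per candidate
#'
#' Prints the aligned amino-acid and codon rows of the pair with the
#' retained enhancer spans marked under the weak member's row.
#'
#' @param report One row of a report tibble.
#' @param alignment The `codon_alignment` of the pair.
#' @return A character vector of text lines.
#' @export
format_report_block <- function(report, alignment) {
  w <- report$weak_member
  s <- report$strong_member
  hits <- report$ese_hits[[1]]
  nc <- nchar(alignment$protein_rows[w])
  marks <- rep(" ", 3 * nc)
  for (k in seq_len(nrow(hits))) {
    span <- (hits$nt_col_start[k] + 1L):hits$nt_col_end[k]
    marks[span] <- "^"
  }
  c(
    sprintf("candidate: weak=%s (%.2f bits) strong=%s (%.2f bits) site=%s",
            w, report$strength_weak, s, report$strength_strong,
            report$site_type),
    sprintf("  %-12s %s", w, alignment$nucleotide_rows[w]),
    sprintf("  %-12s %s", "", paste(marks, collapse = "")),
    sprintf("  %-12s %s", s, alignment$nucleotide_rows[s]),
    sprintf("  diffs: %s",
            paste(sprintf("col%d:%s>%s", report$diffs[[1]]$column,
                          report$diffs[[1]]$aa_i, report$diffs[[1]]$aa_j),
                  collapse = "; "))
  )
}
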
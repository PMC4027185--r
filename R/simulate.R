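#' Construct a window distribution for simulation
#'
#' Either an independence (singleton) model from per-position base
#' probabilities, or a first-order chain from adjacent-pair tables.
#'
#' @param marg Width x 4 matrix of per-position probabilities (A,C,G,T).
#' @param pairs Optional list of `width - 1` adjacent-pair 4x4 probability
#'   tables; when given, a chain distribution is built and `marg` is
#'   derived from the pair tables (overriding any inconsistent input).
#' @return A `window_dist` usable with [sim_splice_windows()].
#' @export
make_window_dist <- function(marg = NULL, pairs = NULL) {
  if (!is.null(pairs)) {
    pairs <- lapply(pairs, function(p) {
      p <- as.matrix(p) / sum(p)
      dimnames(p) <- list(BASES, BASES)
      p
    })
    return(dist_chain(pairs_to_marg(pairs), pairs))
  }
  if (is.null(marg)) abort("supply marg and/or pairs")
  marg <- as.matrix(marg)
  marg <- marg / rowSums(marg)
  colnames(marg) <- BASES
  dist_singleton(marg)
}

#' Reference per-position base probabilities for splice-site signal
#'
#' Consensus-shaped singleton marginals used by the simulators: donor
#' windows peak at the near-invariant GT dinucleotide and the extended
#' consensus around it; acceptor windows carry a pyrimidine tract, the
#' near-invariant AG, and a G-biased first exonic base. These emulate the
#' shape of real site composition; they are not trained on genomic data.
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @return A width x 4 probability matrix.
#' @export
site_signal_params <- function(site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  row <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  if (site_type == "donor") {
    # 3 exonic + 6 intronic (consensus MAG | GTRAGT)
    marg <- rbind(
      row(.35, .35, .20, .10),
      row(.60, .15, .15, .10),
      row(.10, .05, .80, .05),
      row(.01, .01, .97, .01),   # +1 G
      row(.01, .01, .01, .97),   # +2 T
      row(.60, .05, .30, .05),
      row(.70, .10, .10, .10),
      row(.10, .05, .80, .05),
      row(.15, .15, .20, .50)
    )
  } else {
    # 20 intronic (pyrimidine tract ... AG) + 3 exonic
    pyr <- row(.08, .35, .07, .50)
    marg <- rbind(
      matrix(rep(row(.15, .30, .15, .40), 5), ncol = 4, byrow = TRUE),
      matrix(rep(pyr, 13), ncol = 4, byrow = TRUE),
      row(.94, .02, .02, .02),   # -2 A
      row(.02, .02, .94, .02),   # -1 G
      row(.25, .15, .50, .10),   # +1 exonic, G-biased
      row(.25, .25, .25, .25),
      row(.25, .25, .25, .25)
    )
  }
  colnames(marg) <- BASES
  marg
}

#' Simulate splice-site training windows
#'
#' Draws i.i.d. windows from a factored distribution; deterministic per
#' seed.
#'
#' @param dist A `window_dist` from [make_window_dist()], or a `width x 4`
#'   probability matrix (treated as a singleton model).
#' @param n Number of windows (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` windows.
#' @export
sim_splice_windows <- function(dist, n, seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  if (is.matrix(dist)) dist <- make_window_dist(marg = dist)
  withr::with_seed(seed, dist_sample(dist, n))
}

#' Train a reference splice-site model from simulated windows
#'
#' Convenience wrapper: samples a training corpus from
#' [site_signal_params()] and fits [train_maxent()].
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @param n_train Training corpus size (default 2000).
#' @param seed Integer seed.
#' @param constraints Passed to [train_maxent()].
#' @return A `splice_model`.
#' @export
default_site_model <- function(site_type = c("donor", "acceptor"),
                               n_train = 2000L, seed = 100L,
                               constraints = "chain") {
  site_type <- match.arg(site_type)
  spec <- site_window_spec(site_type)
  wins <- sim_splice_windows(site_signal_params(site_type), n_train,
                             seed = seed)
  train_maxent(wins, spec = spec, constraints = constraints)
}

#' Simulate noisy Michaelis-Menten velocity data
#'
#' `v = mm_velocity(Vmax, Km, S) * (1 + eps)` with `eps ~ N(0, noise_cv)`;
#' negative draws are truncated at 0. Deterministic per seed.
#'
#' @param Vmax,Km Generating parameters (uM s^-1, mM).
#' @param S_grid Substrate concentrations in mM; default 12 log-spaced
#'   points spanning 0.01 to 20 mM.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @param enzyme Label stored in the table.
#' @return A tibble with columns `enzyme`, `S`, `v`, `replicate`.
#' @export
sim_mm_data <- function(Vmax, Km, S_grid = NULL, noise_cv = 0,
                        n_replicates = 1L, seed = 1L, enzyme = "sim") {
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  S_grid <- S_grid %||% exp(seq(log(0.01), log(20), length.out = 12))
  df <- tidyr::expand_grid(replicate = seq_len(n_replicates), S = S_grid)
  mu <- mm_velocity(Vmax, Km, df$S)
  v <- withr::with_seed(seed, {
    pmax(0, mu * (1 + rnorm(nrow(df), 0, noise_cv)))
  })
  tibble(enzyme = enzyme, S = df$S, v = v, replicate = df$replicate)
}

# ---------------------------------------------------------------------------
# paralog family generator
# ---------------------------------------------------------------------------

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

syn_codons <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  names(code)[code == code[[codon]]]
}

# sample an intronic flank segment so that the member's full site window
# classifies at the target strength; rejection sampling, bounded
sample_site_flank <- function(model, target, exon_part, cutoffs,
                              max_tries = 500L) {
  il <- model$spec$intronic_len
  site <- model$spec$site_type
  weak_source <- dist_uniform(model$spec$width)
  for (try in seq_len(max_tries)) {
    full <- if (target == "strong") {
      dist_sample(model$signal, 1L)
    } else {
      dist_sample(weak_source, 1L)
    }
    intronic <- if (site == "acceptor") {
      str_sub(full, 1L, il)
    } else {
      str_sub(full, model$spec$exonic_len + 1L)
    }
    win <- if (site == "acceptor") {
      paste0(intronic, exon_part)
    } else {
      paste0(exon_part, intronic)
    }
    label <- classify_strength(score_site(model, win), cutoffs)$label
    if (label == target) return(intronic)
  }
  abort(sprintf("could not sample a %s %s site in %d tries", target, site,
                max_tries))
}

random_nt <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# remove unsanctioned occurrences of the planted hexamers by synonymous
# codon substitution; returns the codon vector or NULL if infeasible
scrub_hexamers <- function(codons, hexamers, allowed_start0 = integer(0),
                           max_rounds = 50L) {
  for (round in seq_len(max_rounds)) {
    seqs <- paste(codons, collapse = "")
    occ <- unlist(lapply(hexamers, function(h) {
      out <- gregexpr(h, seqs, fixed = TRUE)[[1]]
      out[out > 0] - 1L
    }))
    occ <- setdiff(occ, allowed_start0)
    if (length(occ) == 0) return(codons)
    pos <- occ[1]
    touched <- unique((pos:(pos + 5L)) %/% 3L + 1L)
    fixed <- FALSE
    for (ci in sample(touched)) {
      alts <- setdiff(syn_codons(codons[ci]), codons[ci])
      for (alt in sample(alts, length(alts))) {
        trial <- codons
        trial[ci] <- alt
        s2 <- paste(trial, collapse = "")
        occ2 <- unlist(lapply(hexamers, function(h) {
          out <- gregexpr(h, s2, fixed = TRUE)[[1]]
          out[out > 0] - 1L
        }))
        if (!pos %in% setdiff(occ2, allowed_start0)) {
          codons <- trial
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) return(NULL)
  }
  NULL
}

#' Simulate a paralog exon family with planted splicing signals
#'
#' Builds a family of near-identical exon records emulating the screened
#' scenario: one or more members carry an in-frame enhancer hexamer and a
#' weak acceptor site, the others lack the hexamer (ablated at the planted
#' codon) and carry a strong acceptor site. Background divergence between
#' members is strictly synonymous, so the only amino-acid differences are
#' the engineered ablations. Donor sites are strong in all members. Flank
#' site windows are sampled from the supplied trained models so strength is
#' defined in-model rather than by fixed strings.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param n_members Number of members (>= 2), named `m1..mk`.
#' @param exon_len_codons Exon length in codons.
#' @param identity_target Target nucleotide identity between members, in
#'   (0, 1].
#' @param planted Tibble with columns `member`, `hexamer`, `codon`: the
#'   hexamer occupies codons `codon` and `codon + 1` of that member.
#' @param acceptor_strengths Named character vector mapping member to
#'   `"weak"` or `"strong"`; members not named default to `"strong"`.
#' @param flank_len Flank length in nt (>= the models' intronic lengths).
#' @param models Named list with `acceptor` and `donor` splice models used
#'   both to sample and to verify site strength.
#' @param cutoffs Strength cutoffs (bits).
#' @param ablation `"nonsynonymous"` (default; the ablating codon change
#'   also changes the residue, the scenario the screen targets) or
#'   `"synonymous"` (the hexamer is removed without changing the protein,
#'   where the code allows it).
#' @return A list with `records` (named list of [exon_record()]) and
#'   `truth` (list of tibbles: `plants`, `strengths`,
#'   `expected_candidates`).
#' @export
sim_paralog_family <- function(seed, n_members = 2L, exon_len_codons = 40L,
                               identity_target = 0.97,
                               planted = tibble(member = "m1",
                                                hexamer = "GAAGAA",
                                                codon = 10L),
                               acceptor_strengths = c(m1 = "weak"),
                               flank_len = 30L,
                               models,
                               cutoffs = c(3, 6),
                               ablation = c("nonsynonymous", "synonymous")) {
  ablation <- match.arg(ablation)
  if (n_members < 2) abort("n_members must be >= 2")
  members <- paste0("m", seq_len(n_members))
  strengths <- setNames(rep("strong", n_members), members)
  strengths[names(acceptor_strengths)] <- acceptor_strengths
  planted$hexamer <- toupper(planted$hexamer)
  if (any(planted$codon < 1 | planted$codon + 1 > exon_len_codons)) {
    abort("planted codon positions must leave room for the 6-mer inside the exon")
  }
  if (flank_len < models$acceptor$spec$intronic_len ||
      flank_len < models$donor$spec$intronic_len) {
    abort("flank_len shorter than the models' intronic window lengths")
  }
  code <- Biostrings::GENETIC_CODE
  withr::with_seed(seed, {
    base <- sample(sense_codons(), exon_len_codons, replace = TRUE)
    # the exon's final codon feeds the donor window's exonic positions; pin
    # it to a donor-compatible codon so a strong donor site is reachable
    base[exon_len_codons] <- sample(c("AAG", "CAG"), 1L)
    plant_rows <- list()
    member_codons <- setNames(
      rep(list(base), n_members), members
    )
    for (pi in seq_len(nrow(planted))) {
      p <- planted[pi, ]
      c1 <- substr(p$hexamer, 1, 3)
      c2 <- substr(p$hexamer, 4, 6)
      if (code[[c1]] == "*" || code[[c2]] == "*") {
        abort(sprintf(
          "infeasible plant: hexamer %s contains a stop codon in frame",
          p$hexamer
        ))
      }
      carriers <- planted$member[planted$hexamer == p$hexamer &
                                   planted$codon == p$codon]
      for (m in members) {
        if (m %in% carriers) {
          member_codons[[m]][p$codon] <- c1
          member_codons[[m]][p$codon + 1L] <- c2
        } else {
          ab <- ablate_codons(c1, c2, p$hexamer, ablation, code)
          member_codons[[m]][p$codon] <- ab$c1
          member_codons[[m]][p$codon + 1L] <- ab$c2
          plant_rows[[length(plant_rows) + 1L]] <- tibble(
            member = p$member, hexamer = p$hexamer, codon = p$codon,
            ablated_in = m, ablation_type = ab$type
          )
        }
      }
    }
    # background divergence: synonymous-only, away from the planted codons
    # and the pinned donor-boundary codon
    protected <- unique(c(planted$codon, planted$codon + 1L,
                          exon_len_codons))
    n_mut <- round((1 - identity_target) * 3 * exon_len_codons)
    for (m in members) {
      free <- setdiff(seq_len(exon_len_codons), protected)
      done <- 0L
      tries <- 0L
      while (done < n_mut && tries < 20L * n_mut + 20L) {
        tries <- tries + 1L
        ci <- sample(free, 1L)
        alts <- setdiff(syn_codons(member_codons[[m]][ci]),
                        member_codons[[m]][ci])
        if (length(alts) == 0) next
        member_codons[[m]][ci] <- sample(alts, 1L)
        done <- done + 1L
      }
    }
    # scrub unsanctioned hexamer occurrences everywhere
    hexamers <- unique(planted$hexamer)
    for (m in members) {
      allowed <- planted |>
        filter(.data$member == m) |>
        mutate(start0 = 3L * (.data$codon - 1L))
      scrubbed <- scrub_hexamers(member_codons[[m]], hexamers,
                                 allowed_start0 = allowed$start0)
      if (is.null(scrubbed)) {
        abort("infeasible plant: could not remove a spurious hexamer occurrence synonymously")
      }
      member_codons[[m]] <- scrubbed
    }
    # flanks: acceptor window at the exon start, donor at the exon end
    records <- list()
    strength_rows <- list()
    for (m in members) {
      exon <- paste(member_codons[[m]], collapse = "")
      acc_flank <- sample_site_flank(
        models$acceptor, strengths[[m]],
        exon_part = str_sub(exon, 1L, models$acceptor$spec$exonic_len),
        cutoffs = cutoffs
      )
      don_flank <- sample_site_flank(
        models$donor, "strong",
        exon_part = str_sub(exon, -models$donor$spec$exonic_len),
        cutoffs = cutoffs
      )
      up <- paste0(random_nt(flank_len - nchar(acc_flank)), acc_flank)
      down <- paste0(don_flank, random_nt(flank_len - nchar(don_flank)))
      rec <- exon_record(m, exon, upstream_flank = up,
                         downstream_flank = down, phase = 0L)
      records[[m]] <- rec
      strength_rows[[m]] <- tibble(
        member = m,
        target = strengths[[m]],
        acceptor_score = site_strength(rec, "acceptor", models$acceptor,
                                       cutoffs)$score
      )
    }
    plants <- bind_rows(plant_rows)
    expected <- if (nrow(plants) == 0) {
      tibble(weak_member = character(0), strong_member = character(0),
             site_type = character(0), codon = integer(0))
    } else {
      plants |>
        filter(.data$ablation_type == "nonsynonymous",
               strengths[.data$member] == "weak",
               strengths[.data$ablated_in] == "strong") |>
        mutate(weak_member = .data$member,
               strong_member = .data$ablated_in,
               site_type = "acceptor") |>
        select("weak_member", "strong_member", "site_type", "codon") |>
        distinct()
    }
    list(
      records = records,
      truth = list(
        plants = plants,
        strengths = bind_rows(strength_rows),
        expected_candidates = expected
      )
    )
  })
}

# choose ablated codons for a plant: destroy the hexamer, synonymously if
# requested and possible, else by a conservative residue change
ablate_codons <- function(c1, c2, hexamer, ablation, code) {
  destroys <- function(a, b) paste0(a, b) != hexamer
  if (ablation == "synonymous") {
    for (alt in setdiff(syn_codons(c1), c1)) {
      if (destroys(alt, c2)) return(list(c1 = alt, c2 = c2, type = "synonymous"))
    }
    for (alt in setdiff(syn_codons(c2), c2)) {
      if (destroys(c1, alt)) return(list(c1 = c1, c2 = alt, type = "synonymous"))
    }
    # fall through to nonsynonymous when degeneracy cannot break the motif
  }
  aa1 <- code[[c1]]
  candidates <- setdiff(sense_codons(), syn_codons(c1))
  for (alt in candidates) {
    if (destroys(alt, c2)) {
      return(list(c1 = alt, c2 = c2, type = "nonsynonymous"))
    }
  }
  abort("infeasible plant: no ablating codon found")
}
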
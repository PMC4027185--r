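#' Exon record
#'
#' One paralog family member: the exon sequence, its intronic flanks, the
#' reading-frame phase (number of nucleotides in the leading partial codon)
#' and free-form gene metadata.
#'
#' @param seq_id Unique identifier.
#' @param exon_seq Exon nucleotide string.
#' @param upstream_flank,downstream_flank Intronic flank strings (may be
#'   empty).
#' @param phase Integer 0, 1 or 2: offset of the first complete codon.
#' @param meta Optional named list of labels (gene, transcript, domain).
#' @return An object of class `exon_record`.
#' @export
exon_record <- function(seq_id, exon_seq, upstream_flank = "",
                        downstream_flank = "", phase = 0L, meta = list()) {
  phase <- as.integer(phase)
  if (!phase %in% 0:2) abort("phase must be 0, 1 or 2")
  exon_seq <- toupper(exon_seq)
  if (nchar(exon_seq) - phase < 3) {
    abort("exon must contain at least one complete codon after the phase offset")
  }
  structure(
    list(seq_id = seq_id, exon_seq = exon_seq,
         upstream_flank = toupper(upstream_flank),
         downstream_flank = toupper(downstream_flank),
         phase = phase, meta = meta),
    class = "exon_record"
  )
}

#' @export
print.exon_record <- function(x, ...) {
  cat(sprintf(
    "<exon_record> %s  exon %d nt (phase %d), flanks %d/%d nt\n",
    x$seq_id, nchar(x$exon_seq), x$phase,
    nchar(x$upstream_flank), nchar(x$downstream_flank)
  ))
  invisible(x)
}

#' Build exon records from a descriptor table and sequences
#'
#' @param descr A data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive exon coordinates within the FASTA record) and `phase`.
#' @param seqs A tibble from [read_fasta()].
#' @return A named list of [exon_record()] objects.
#' @export
exon_records_from_table <- function(descr, seqs) {
  recs <- lapply(seq_len(nrow(descr)), function(i) {
    row <- descr[i, ]
    full <- seqs$seq[match(row$seq_id, seqs$id)]
    if (is.na(full)) abort(paste0("sequence not found: ", row$seq_id))
    exon_record(
      seq_id = row$seq_id,
      exon_seq = str_sub(full, row$start, row$end),
      upstream_flank = str_sub(full, 1L, row$start - 1L),
      downstream_flank = str_sub(full, row$end + 1L),
      phase = row$phase
    )
  })
  setNames(recs, descr$seq_id)
}

#' Translate a coding sequence
#'
#' Standard genetic code. `phase` nucleotides are skipped before the first
#' codon; a trailing partial codon is dropped. Stop codons translate to
#' `*`; codons containing any non-ACGT character translate to `X`.
#'
#' @param cds Nucleotide string.
#' @param phase Integer 0, 1 or 2.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, phase = 0L) {
  phase <- as.integer(phase)
  if (!phase %in% 0:2) abort("phase must be 0, 1 or 2")
  cds <- toupper(cds)
  n <- nchar(cds) - phase
  if (n < 3) abort("fewer than one complete codon after the phase offset")
  n_codon <- n %/% 3L
  starts <- phase + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# coding region of an exon record: complete codons after the phase offset
coding_region <- function(rec) {
  n <- nchar(rec$exon_seq) - rec$phase
  n_codon <- n %/% 3L
  str_sub(rec$exon_seq, rec$phase + 1L, rec$phase + 3L * n_codon)
}

#' Codon-aware global alignment of two exon records
#'
#' Translates each record's complete codons, aligns the proteins globally
#' (Needleman-Wunsch with affine gaps via `Biostrings::pairwiseAlignment`)
#' and back-threads the nucleotides codon-per-residue, so each gap residue
#' becomes a `---` codon gap.
#'
#' @param a,b [exon_record()] objects.
#' @param sub_matrix Substitution matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return An object of class `codon_alignment` with fields `members`,
#'   `protein_rows`, `nucleotide_rows`, `score`, `column_map`.
#' @export
align_pair <- function(a, b, sub_matrix = "BLOSUM62", gap_open = 10,
                       gap_extend = 0.5) {
  pa_str <- translate_cds(coding_region(a))
  pb_str <- translate_cds(coding_region(b))
  if (nchar(pa_str) == 0 || nchar(pb_str) == 0) {
    abort("empty translation; records must contain complete codons")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa_str), Biostrings::AAString(pb_str),
    substitutionMatrix = sub_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  row_a <- as.character(Biostrings::alignedPattern(al))
  row_b <- as.character(Biostrings::alignedSubject(al))
  build_codon_alignment(
    members = c(a$seq_id, b$seq_id),
    protein_rows = c(row_a, row_b),
    cds = c(coding_region(a), coding_region(b)),
    phases = c(a$phase, b$phase),
    score = Biostrings::score(al)
  )
}

# thread nucleotide codons under an aligned protein row
backthread <- function(protein_row, cds) {
  res <- chars(protein_row)
  codons <- character(length(res))
  k <- 0L
  for (i in seq_along(res)) {
    if (res[i] == "-") {
      codons[i] <- "---"
    } else {
      codons[i] <- substr(cds, 3L * k + 1L, 3L * k + 3L)
      k <- k + 1L
    }
  }
  paste(codons, collapse = "")
}

build_codon_alignment <- function(members, protein_rows, cds, phases,
                                  score = NA_real_) {
  nt_rows <- mapply(backthread, protein_rows, cds, USE.NAMES = FALSE)
  # column_map: per member, original codon index (1-based, within the coding
  # region) for every protein column; NA at gaps. Phases recorded so exon
  # coordinates can be recovered.
  column_map <- lapply(seq_along(members), function(i) {
    res <- chars(protein_rows[i])
    idx <- rep(NA_integer_, length(res))
    idx[res != "-"] <- seq_len(sum(res != "-"))
    idx
  })
  names(column_map) <- members
  structure(
    list(
      members = members,
      protein_rows = setNames(protein_rows, members),
      nucleotide_rows = setNames(nt_rows, members),
      phases = setNames(as.integer(phases), members),
      column_map = column_map,
      score = score
    ),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf(
    "<codon_alignment> %d members, %d columns, score %.1f\n",
    length(x$members), nchar(x$protein_rows[1]), x$score
  ))
  for (m in x$members) cat(sprintf("  %-12s %s\n", m, x$protein_rows[m]))
  invisible(x)
}

#' Progressive multiple codon alignment against an anchor
#'
#' Aligns every record pairwise against the first record and merges the
#' anchor gap patterns (taking, at each anchor position, the longest
#' insertion seen in any pair). Adequate for highly similar paralog
#' families; not a general multiple aligner.
#'
#' @param records List of [exon_record()] objects (>= 2); the first is the
#'   anchor.
#' @inheritParams align_pair
#' @return A `codon_alignment` over all members.
#' @export
align_family <- function(records, sub_matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  if (length(records) < 2) abort("need at least 2 records")
  if (length(records) == 2) {
    return(align_pair(records[[1]], records[[2]], sub_matrix, gap_open,
                      gap_extend))
  }
  anchor <- records[[1]]
  pairs <- lapply(records[-1], function(r) {
    align_pair(anchor, r, sub_matrix, gap_open, gap_extend)
  })
  anchor_prot <- translate_cds(coding_region(anchor))
  n_anchor <- nchar(anchor_prot)
  # insertion lengths relative to anchor, slot g = before anchor residue g+1
  ins_len <- function(al) {
    arow <- chars(al$protein_rows[1])
    slots <- integer(n_anchor + 1L)
    pos <- 0L
    run <- 0L
    for (ch in arow) {
      if (ch == "-") run <- run + 1L else {
        slots[pos + 1L] <- run
        run <- 0L
        pos <- pos + 1L
      }
    }
    slots[n_anchor + 1L] <- run
    slots
  }
  all_slots <- do.call(pmax, lapply(pairs, ins_len))
  pad_row <- function(al, member_idx) {
    arow <- chars(al$protein_rows[1])
    mrow <- chars(al$protein_rows[member_idx])
    out <- character(0)
    pos <- 0L
    i <- 1L
    while (pos <= n_anchor) {
      # consume this slot's insertions in the pair, pad to all_slots
      got <- 0L
      while (i <= length(arow) && arow[i] == "-") {
        out <- c(out, mrow[i])
        got <- got + 1L
        i <- i + 1L
      }
      out <- c(out, rep("-", all_slots[pos + 1L] - got))
      if (pos < n_anchor) {
        out <- c(out, mrow[i])
        i <- i + 1L
      }
      pos <- pos + 1L
    }
    paste(out, collapse = "")
  }
  anchor_padded <- {
    out <- character(0)
    for (g in seq_len(n_anchor + 1L)) {
      out <- c(out, rep("-", all_slots[g]))
      if (g <= n_anchor) out <- c(out, substr(anchor_prot, g, g))
    }
    paste(out, collapse = "")
  }
  rows <- c(anchor_padded,
            vapply(pairs, pad_row, character(1), member_idx = 2L))
  members <- vapply(records, function(r) r$seq_id, character(1))
  build_codon_alignment(
    members = members,
    protein_rows = rows,
    cds = vapply(records, coding_region, character(1)),
    phases = vapply(records, function(r) r$phase, integer(1)),
    score = sum(vapply(pairs, function(p) p$score, numeric(1)))
  )
}

#' Column-wise differences between two alignment members
#'
#' One row per protein-alignment column where the codons differ:
#' `nonsynonymous` if the amino acids differ, `synonymous` if only the
#' codons differ, `gap` if either member is gapped.
#'
#' @param alignment A `codon_alignment`.
#' @param i,j Member ids.
#' @return A tibble with columns `column` (1-based protein column), `kind`,
#'   `aa_i`, `aa_j`, `codon_i`, `codon_j`.
#' @export
diff_columns <- function(alignment, i, j) {
  if (!i %in% alignment$members) abort(paste0("unknown member: ", i))
  if (!j %in% alignment$members) abort(paste0("unknown member: ", j))
  pi <- chars(alignment$protein_rows[i])
  pj <- chars(alignment$protein_rows[j])
  nc <- length(pi)
  ci <- substring(alignment$nucleotide_rows[i], 3 * (1:nc) - 2, 3 * (1:nc))
  cj <- substring(alignment$nucleotide_rows[j], 3 * (1:nc) - 2, 3 * (1:nc))
  differ <- which(ci != cj)
  kind <- vapply(differ, function(k) {
    if (pi[k] == "-" || pj[k] == "-") "gap"
    else if (pi[k] != pj[k]) "nonsynonymous"
    else "synonymous"
  }, character(1))
  tibble(
    column = differ,
    kind = kind,
    aa_i = pi[differ],
    aa_j = pj[differ],
    codon_i = ci[differ],
    codon_j = cj[differ]
  )
}

#' @export
tidy.codon_alignment <- function(x, ...) {
  nc <- nchar(x$protein_rows[1])
  bind_rows(lapply(x$members, function(m) {
    tibble(
      member = m,
      column = seq_len(nc),
      aa = chars(x$protein_rows[m]),
      codon = substring(x$nucleotide_rows[m], 3 * (1:nc) - 2, 3 * (1:nc)),
      source_codon = x$column_map[[m]]
    )
  }))
}

#' Percent identity of an alignment (protein level)
#'
#' @param alignment A `codon_alignment`.
#' @param i,j Member ids; default the first two members.
#' @return Fraction of non-gap columns with identical residues.
#' @export
alignment_identity <- function(alignment, i = NULL, j = NULL) {
  i <- i %||% alignment$members[1]
  j <- j %||% alignment$members[2]
  pi <- chars(alignment$protein_rows[i])
  pj <- chars(alignment$protein_rows[j])
  ok <- pi != "-" & pj != "-"
  mean(pi[ok] == pj[ok])
}
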
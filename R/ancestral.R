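#' Multi-species alignment with ancestral node rows
#'
#' Holds an aligned set of leaf and reconstructed internal-node sequences,
#' the matching tree, a reference row defining coordinates, and the
#' reference exon interval in ungapped reference coordinates.
#'
#' @param rows Named character vector of equal-length aligned sequences
#'   (leaves plus internal nodes).
#' @param tree An `ape::phylo` tree or newick string whose labels match the
#'   row names (rows without tree labels are tolerated and vice versa, with
#'   warnings downstream).
#' @param ref_label Name of the reference row.
#' @param ref_exon Length-2 integer vector, 0-based half-open exon interval
#'   in ungapped reference coordinates.
#' @param flags Optional character vector of alignment-level flags.
#' @return An object of class `node_alignment`.
#' @export
node_alignment <- function(rows, tree = NULL, ref_label, ref_exon,
                           flags = character(0)) {
  if (is.null(names(rows)) || any(names(rows) == "")) {
    abort("rows must be a named character vector")
  }
  if (length(unique(nchar(rows))) != 1) {
    abort("all alignment rows must have equal length")
  }
  if (!ref_label %in% names(rows)) {
    abort(paste0("reference row not found: ", ref_label))
  }
  rows <- toupper(rows)
  ref_len <- nchar(gsub("-", "", rows[[ref_label]]))
  ref_exon <- as.integer(ref_exon)
  if (ref_exon[1] < 0 || ref_exon[2] > ref_len || ref_exon[1] >= ref_exon[2]) {
    abort("ref_exon must be a non-empty 0-based half-open interval within the reference")
  }
  if (is.character(tree)) tree <- label_internals(ape::read.tree(text = tree))
  structure(
    list(rows = rows, tree = tree, ref_label = ref_label,
         ref_exon = ref_exon, flags = flags),
    class = "node_alignment"
  )
}

#' @export
print.node_alignment <- function(x, ...) {
  cat(sprintf(
    "<node_alignment> %d rows x %d columns, ref=%s exon [%d,%d)%s\n",
    length(x$rows), nchar(x$rows[1]), x$ref_label,
    x$ref_exon[1], x$ref_exon[2],
    if (length(x$flags)) paste0("  flags: ", paste(x$flags, collapse = ",")) else ""
  ))
  invisible(x)
}

# alignment column (1-based) of each ungapped reference position (1-based)
ref_col_map <- function(na) {
  which(chars(na$rows[[na$ref_label]]) != "-")
}

#' Trim a node alignment to the reference exon plus flanks
#'
#' Restricts the alignment columns to the interval spanning the exon plus
#' `flank` nucleotides on each side, measured in ungapped reference
#' coordinates and mapped through the reference row's gaps. A flank that
#' runs past the available reference sequence is truncated and flagged
#' `short_flank` rather than erroring. Idempotent at a fixed flank.
#'
#' @param na A [node_alignment()].
#' @param flank Flank length in nucleotides (>= 0), default 30.
#' @return A trimmed `node_alignment` with `ref_exon` recomputed.
#' @export
trim_to_exon <- function(na, flank = 30L) {
  if (flank < 0) abort("flank must be >= 0")
  cmap <- ref_col_map(na)
  ref_len <- length(cmap)
  u_start <- na$ref_exon[1] - flank      # 0-based
  u_end <- na$ref_exon[2] + flank
  flags <- setdiff(na$flags, "short_flank")
  if (u_start < 0 || u_end > ref_len) {
    flags <- c(flags, "short_flank")
    u_start <- max(0L, u_start)
    u_end <- min(ref_len, u_end)
  }
  col_start <- cmap[u_start + 1L]
  col_end <- cmap[u_end]                  # last included column
  rows <- vapply(na$rows, function(s) substr(s, col_start, col_end),
                 character(1))
  node_alignment(
    rows = rows, tree = na$tree, ref_label = na$ref_label,
    ref_exon = c(na$ref_exon[1] - u_start, na$ref_exon[2] - u_start),
    flags = flags
  )
}

#' Scan every node row for motifs and splice-site strength
#'
#' Exon boundaries are projected from the reference row through alignment
#' columns onto each node. Each node's exon body (degapped) is scanned for
#' the motif sets; acceptor and donor windows are read off the node's
#' characters at the reference window columns and scored unless they
#' contain gaps (flag `gap_in_site_window`) or the alignment lacks flank
#' columns (flag `short_flank`).
#'
#' @param na A (typically trimmed) [node_alignment()].
#' @param pwms,hexsets Motif sets; PWM hits are counted per matrix,
#'   hexamer hits summed over all sets.
#' @param models Named list with elements `acceptor` and/or `donor`.
#' @param cutoffs Strength cutoffs passed to [classify_strength()].
#' @return A tibble, one row per node: `node`, `acceptor_score`,
#'   `acceptor_label`, `donor_score`, `donor_label`, `n_<matrix>` per PWM,
#'   `hexamer_hits`, `flags`.
#' @export
scan_nodes <- function(na, pwms = list(), hexsets = list(), models = list(),
                       cutoffs = c(3, 6)) {
  cmap <- ref_col_map(na)
  ref_len <- length(cmap)
  ex <- na$ref_exon
  exon_cols <- cmap[ex[1] + 1L]:cmap[ex[2]]
  site_cols <- function(site) {
    model <- models[[site]]
    if (is.null(model)) return(NULL)
    el <- model$spec$exonic_len
    il <- model$spec$intronic_len
    u <- if (site == "acceptor") {
      (ex[1] - il):(ex[1] + el - 1L)        # 0-based ref positions
    } else {
      (ex[2] - el):(ex[2] + il - 1L)
    }
    if (any(u < 0) || any(u >= ref_len)) return("short")
    cmap[u + 1L]
  }
  acc_cols <- site_cols("acceptor")
  don_cols <- site_cols("donor")
  profs <- lapply(names(na$rows), function(nl) {
    row <- chars(na$rows[[nl]])
    flags <- character(0)
    exon_body <- paste(row[exon_cols][row[exon_cols] != "-"], collapse = "")
    score_one <- function(cols, site) {
      if (is.null(cols)) return(list(score = NA_real_, label = NA_character_))
      if (identical(cols, "short")) {
        flags <<- union(flags, "short_flank")
        return(list(score = NA_real_, label = NA_character_))
      }
      win_chars <- row[cols]
      if (any(win_chars == "-")) {
        flags <<- union(flags, "gap_in_site_window")
        return(list(score = NA_real_, label = NA_character_))
      }
      win <- paste(win_chars, collapse = "")
      if (!grepl("^[ACGT]+$", win)) {
        flags <<- union(flags, "ambiguous_site_window")
        return(list(score = NA_real_, label = NA_character_))
      }
      sc <- score_site(models[[site]], win)
      list(score = sc, label = classify_strength(sc, cutoffs)$label)
    }
    acc <- score_one(acc_cols, "acceptor")
    don <- score_one(don_cols, "donor")
    pwm_counts <- if (length(pwms) == 0) integer(0) else setNames(
      vapply(pwms, function(p) nrow(scan_pwm(exon_body, p, seq_id = nl)),
             integer(1)),
      paste0("n_", vapply(pwms, function(p) p$name, character(1)))
    )
    hex_count <- sum(vapply(hexsets, function(h) {
      nrow(scan_hexamers(exon_body, h, seq_id = nl))
    }, integer(1)))
    c(
      list(node = nl, acceptor_score = acc$score, acceptor_label = acc$label,
           donor_score = don$score, donor_label = don$label),
      as.list(pwm_counts),
      list(hexamer_hits = as.integer(hex_count),
           flags = paste(flags, collapse = ";"))
    )
  })
  bind_rows(lapply(profs, as_tibble))
}

#' Per-node motif hit positions as BED-ready tibbles
#'
#' Positions are in each node's own degapped exon-body coordinates
#' (0-based half-open).
#'
#' @inheritParams scan_nodes
#' @return A tibble of hits over all nodes.
#' @export
scan_node_hits <- function(na, pwms = list(), hexsets = list()) {
  cmap <- ref_col_map(na)
  ex <- na$ref_exon
  exon_cols <- cmap[ex[1] + 1L]:cmap[ex[2]]
  bind_rows(lapply(names(na$rows), function(nl) {
    row <- chars(na$rows[[nl]])
    exon_body <- paste(row[exon_cols][row[exon_cols] != "-"], collapse = "")
    scan_motifs(exon_body, pwms = pwms, hexsets = hexsets, seq_id = nl)
  }))
}

#' Annotate a tree with per-node splice-site scores
#'
#' Writes the scores into the newick string as `[&...]` comment blocks
#' following each matching tip or node label, and returns a companion
#' table. Labels in the tree without a profile row are left unannotated
#' with a warning.
#'
#' @param profiles Output of [scan_nodes()].
#' @param tree An `ape::phylo` tree.
#' @return A list with elements `newick` (annotated string) and `table`
#'   (the profiles tibble).
#' @export
annotate_tree <- function(profiles, tree) {
  tree <- label_internals(tree)
  nwk <- ape::write.tree(tree)
  labels <- c(tree$tip.label, tree$node.label)
  missing <- setdiff(labels, profiles$node)
  if (length(missing)) {
    warn(paste0("no profile for tree label(s): ",
                paste(missing, collapse = ", ")))
  }
  for (lab in intersect(labels, profiles$node)) {
    p <- profiles[profiles$node == lab, ]
    ann <- sprintf("[&acceptor=%s,donor=%s,hex=%d]",
                   format(p$acceptor_score[1], digits = 6),
                   format(p$donor_score[1], digits = 6),
                   p$hexamer_hits[1])
    # tip labels follow "(" or ","; internal labels follow ")"
    nwk <- sub(
      paste0("(^|[(,)])", lab, "([:,);])"),
      paste0("\\1", lab, ann, "\\2"),
      nwk
    )
  }
  list(newick = nwk, table = profiles)
}

#' Parse a newick string annotated by [annotate_tree()]
#'
#' @param nwk Annotated newick string.
#' @return A list with `tree` (an `ape::phylo`, annotations stripped) and
#'   `annotations` (tibble: `node`, `acceptor_score`, `donor_score`,
#'   `hexamer_hits`).
#' @export
read_annotated_newick <- function(nwk) {
  m <- gregexpr("([A-Za-z0-9_.|-]+)\\[&([^]]*)\\]", nwk)[[1]]
  ann <- tibble(node = character(0), acceptor_score = numeric(0),
                donor_score = numeric(0), hexamer_hits = integer(0))
  if (m[1] != -1) {
    pieces <- regmatches(nwk, gregexpr("([A-Za-z0-9_.|-]+)\\[&([^]]*)\\]", nwk))[[1]]
    ann <- bind_rows(lapply(pieces, function(p) {
      lab <- sub("\\[.*$", "", p)
      body <- sub("^.*\\[&", "", sub("\\]$", "", p))
      kv <- strsplit(strsplit(body, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      vals <- setNames(
        vapply(kv, `[`, character(1), 2L),
        vapply(kv, `[`, character(1), 1L)
      )
      tibble(
        node = lab,
        acceptor_score = suppressWarnings(as.numeric(vals[["acceptor"]])),
        donor_score = suppressWarnings(as.numeric(vals[["donor"]])),
        hexamer_hits = as.integer(vals[["hex"]])
      )
    }))
  }
  clean <- gsub("\\[&[^]]*\\]", "", nwk)
  tree <- ape::read.tree(text = clean)
  list(tree = tree, annotations = ann)
}
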
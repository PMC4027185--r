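#' Read sequences from a FASTA file
#'
#' Reads nucleotide (or aligned) FASTA. Sequences are uppercased and RNA `U`
#' is normalised to `T`; gap characters (`-`) are preserved so alignment
#' FASTA round-trips. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate sequence ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq`, or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a newick tree, labelling unnamed internal nodes
#'
#' Internal nodes without labels are assigned deterministic labels
#' `N1 .. Nk` in node-index (root-first) order.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree with all internal nodes labelled.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("newick file not found: ", path))
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    abort(paste0("newick parse error in ", path, ": ", conditionMessage(e)))
  })
  if (is.null(tr)) abort(paste0("newick parse error in ", path))
  label_internals(tr)
}

label_internals <- function(tr) {
  nn <- tr$Nnode
  if (is.null(tr$node.label)) tr$node.label <- rep("", nn)
  blank <- is.na(tr$node.label) | tr$node.label == ""
  tr$node.label[blank] <- paste0("N", which(blank))
  tr
}

#' Read a position weight matrix file
#'
#' Format: a comment header `# name=<id> alphabet=ACGT` followed by one row
#' per motif position with four tab-separated real scores in A, C, G, T
#' order.
#'
#' @param path Path to a PWM TSV file.
#' @return A [pwm()] object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nm <- sub(".*name=([^ \t]+).*", "\\1", hdr[1])
  body <- lines[!grepl("^#", lines) & nzchar(str_trim(lines))]
  mat <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (ncol(mat) != 4) abort(paste0("PWM rows must have 4 columns: ", path))
  colnames(mat) <- BASES
  pwm(nm, mat)
}

#' Write a position weight matrix file
#'
#' @param x A [pwm()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name=%s alphabet=ACGT", x$name), con)
  apply(x$matrix, 1, function(r) {
    writeLines(paste(sprintf("%.17g", r), collapse = "\t"), con)
  })
  invisible(path)
}

#' Read a hexamer set file
#'
#' Two-column TSV `hexamer<TAB>score`; the score column is optional.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @param name Set name; defaults to the file name without extension.
#' @param kind Motif kind, `"ESE_HEX"` or `"ESS_HEX"`.
#' @return A [hexamer_set()] object.
#' @export
read_hexamers <- function(path, name = NULL,
                          kind = c("ESE_HEX", "ESS_HEX")) {
  kind <- match.arg(kind)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(str_trim(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  members <- toupper(vapply(parts, `[`, character(1), 1L))
  scores <- vapply(parts, function(p) {
    if (length(p) >= 2) as.numeric(p[2]) else NA_real_
  }, numeric(1))
  if (all(is.na(scores))) scores <- NULL else scores <- setNames(scores, members)
  hexamer_set(name, members, scores = scores, kind = kind)
}

#' Write motif hits as BED6 or TSV
#'
#' BED output is 0-based half-open per the BED standard; TSV output is
#' 1-based inclusive. Both carry a commented provenance header.
#'
#' @param hits A tibble of motif hits from [scan_pwm()] / [scan_hexamers()].
#' @param path Output path.
#' @param format `"bed"` or `"tsv"`.
#' @param params Optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("bed", "tsv"), params = list()) {
  format <- match.arg(format)
  hdr <- sprintf(
    "# splicescreen %s hits%s",
    utils::packageVersion("splicescreen"),
    if (length(params)) {
      paste0(" | ", paste(names(params), unlist(params), sep = "=",
                          collapse = " "))
    } else ""
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "bed") {
    apply_rows <- sprintf(
      "%s\t%d\t%d\t%s\t%g\t+",
      hits$seq_id, hits$start, hits$end, hits$motif_name, hits$score
    )
    writeLines(apply_rows, con)
  } else {
    writeLines("seq_id\tstart\tend\tmotif_name\tscore\tkind", con)
    writeLines(sprintf(
      "%s\t%d\t%d\t%s\t%g\t%s",
      hits$seq_id, hits$start + 1L, hits$end, hits$motif_name, hits$score,
      hits$kind
    ), con)
  }
  invisible(path)
}

#' Read a key=value configuration file
#'
#' TOML-style flat `key = value` pairs; `#` comments ignored. Values that
#' parse as numbers become numeric.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- str_trim(kv[1])
    val <- str_trim(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
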
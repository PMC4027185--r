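# 3-row toy used for the trimming fixtures: reference with and without gaps
toy_alignment <- function(gapped = FALSE) {
  set.seed(83)
  ref <- random_seq(100)
  if (!gapped) {
    rows <- c(ref = ref, n1 = random_seq(100), n2 = random_seq(100))
  } else {
    # 5 gap columns inside the flank region upstream of the exon
    ref_g <- paste0(substr(ref, 1, 33), "-----", substr(ref, 34, 100))
    rows <- c(ref = ref_g, n1 = random_seq(105), n2 = random_seq(105))
  }
  node_alignment(rows, tree = "(n1,n2)ref;", ref_label = "ref",
                 ref_exon = c(40L, 60L))
}

test_that("trim_to_exon selects the exon plus flank columns", {
  na <- toy_alignment()
  tr <- trim_to_exon(na, flank = 10)
  expect_equal(nchar(tr$rows[["ref"]]), 40L)
  expect_equal(tr$rows[["ref"]], substr(na$rows[["ref"]], 31, 70))
  expect_equal(tr$ref_exon, c(10L, 30L))
  # flank 0 gives exactly the exon span
  tr0 <- trim_to_exon(na, flank = 0)
  expect_equal(nchar(tr0$rows[["ref"]]), 20L)
  expect_equal(tr0$ref_exon, c(0L, 20L))
})

test_that("reference gaps inside the flank widen the trimmed block", {
  na <- toy_alignment(gapped = TRUE)
  tr <- trim_to_exon(na, flank = 10)
  # 40 reference nt plus the 5 gap columns that fall inside the window
  expect_equal(nchar(tr$rows[["ref"]]), 45L)
  expect_equal(gsub("-", "", tr$rows[["ref"]]),
               substr(gsub("-", "", na$rows[["ref"]]), 31, 70))
  expect_equal(tr$ref_exon, c(10L, 30L))
})

test_that("trim_to_exon is idempotent and only selects columns", {
  na <- toy_alignment(gapped = TRUE)
  t1 <- trim_to_exon(na, flank = 12)
  t2 <- trim_to_exon(t1, flank = 12)
  expect_identical(t1$rows, t2$rows)
  expect_identical(t1$ref_exon, t2$ref_exon)
  # no sequence mutation: every trimmed row is a substring of its original
  for (m in names(na$rows)) {
    expect_true(grepl(t1$rows[[m]], na$rows[[m]], fixed = TRUE))
  }
})

test_that("a flank larger than the available reference is truncated and flagged", {
  na <- toy_alignment()
  tr <- trim_to_exon(na, flank = 50)
  expect_true("short_flank" %in% tr$flags)
  expect_equal(nchar(tr$rows[["ref"]]), 100L)
  expect_equal(tr$ref_exon, c(40L, 60L))
})

test_that("scan_nodes on one row matches direct motif and splice calls", {
  models <- ss_test_models()
  fam <- sim_paralog_family(seed = 31, models = models)
  r <- fam$records$m1
  full <- paste0(r$upstream_flank, r$exon_seq, r$downstream_flank)
  na <- node_alignment(
    rows = c(only = full), tree = "(only);", ref_label = "only",
    ref_exon = c(nchar(r$upstream_flank),
                 nchar(r$upstream_flank) + nchar(r$exon_seq))
  )
  hx <- plant_hexset()
  p <- pwm("toy", matrix(c(2, 0, 0, 0, 0, 0, 0, 2), 2, byrow = TRUE),
           threshold = 0.9)
  prof <- scan_nodes(na, pwms = list(p), hexsets = list(hx), models = models)
  expect_equal(prof$acceptor_score, score_site(
    models$acceptor,
    extract_site_window(r$exon_seq, r$upstream_flank, site_type = "acceptor")
  ))
  expect_equal(prof$donor_score, score_site(
    models$donor,
    extract_site_window(r$exon_seq, downstream_flank = r$downstream_flank,
                        site_type = "donor")
  ))
  expect_equal(prof$hexamer_hits, nrow(scan_hexamers(r$exon_seq, hx)))
  expect_equal(prof$n_toy, nrow(scan_pwm(r$exon_seq, p)))
  expect_equal(prof$flags, "")
})

test_that("gaps in a node's site window suppress the score with a flag", {
  models <- ss_test_models()
  fam <- sim_paralog_family(seed = 32, models = models)
  r <- fam$records$m1
  full <- paste0(r$upstream_flank, r$exon_seq, r$downstream_flank)
  up_len <- nchar(r$upstream_flank)
  gapped <- paste0(substr(full, 1, up_len - 3), "-",
                   substr(full, up_len - 1, nchar(full)))
  na <- node_alignment(
    rows = c(ref = full, anc = gapped), tree = "(anc)ref;",
    ref_label = "ref",
    ref_exon = c(up_len, up_len + nchar(r$exon_seq))
  )
  prof <- scan_nodes(na, models = models)
  anc <- prof[prof$node == "anc", ]
  expect_true(is.na(anc$acceptor_score))
  expect_match(anc$flags, "gap_in_site_window")
  expect_false(is.na(anc$donor_score))
  ref <- prof[prof$node == "ref", ]
  expect_false(is.na(ref$acceptor_score))
})

test_that("a hexamer planted in one clade is seen in exactly that clade", {
  models <- ss_test_models()
  fam <- sim_paralog_family(seed = 33, models = models)
  r <- fam$records$m1   # carries GAAGAA at codon 10 (nt 27, 0-based)
  with_hex <- paste0(r$upstream_flank, r$exon_seq, r$downstream_flank)
  exon_no <- paste0(substr(r$exon_seq, 1, 27), "TCTTCA",
                    substr(r$exon_seq, 34, nchar(r$exon_seq)))
  without_hex <- paste0(r$upstream_flank, exon_no, r$downstream_flank)
  # 6 leaves + 5 internal nodes; clade under X = {l1, l2, l3, X, X1}
  rows <- c(
    l1 = with_hex, l2 = with_hex, l3 = with_hex,
    l4 = without_hex, l5 = without_hex, l6 = without_hex,
    X = with_hex, X1 = with_hex, Y = without_hex, Y1 = without_hex,
    R = without_hex
  )
  na <- node_alignment(
    rows, tree = "(((l1,l2)X1,l3)X,((l4,l5)Y1,l6)Y)R;", ref_label = "l1",
    ref_exon = c(nchar(r$upstream_flank),
                 nchar(r$upstream_flank) + nchar(r$exon_seq))
  )
  prof <- scan_nodes(na, hexsets = list(plant_hexset()), models = models)
  carriers <- prof$node[prof$hexamer_hits >= 1]
  expect_setequal(carriers, c("l1", "l2", "l3", "X", "X1"))
})

test_that("annotated newick round-trips scores and warns on missing nodes", {
  models <- ss_test_models()
  fam <- sim_paralog_family(seed = 34, models = models)
  r <- fam$records$m1
  full <- paste0(r$upstream_flank, r$exon_seq, r$downstream_flank)
  tree <- ape::read.tree(text = "(((l1,l2)X1,l3)X,((l4,l5)Y1,l6)Y)R;")
  rows <- setNames(rep(full, 11),
                   c("l1", "l2", "l3", "l4", "l5", "l6",
                     "X1", "X", "Y1", "Y", "R"))
  na <- node_alignment(rows, tree = tree, ref_label = "l1",
                       ref_exon = c(nchar(r$upstream_flank),
                                    nchar(r$upstream_flank) +
                                      nchar(r$exon_seq)))
  prof <- scan_nodes(na, hexsets = list(plant_hexset()), models = models)
  ann <- annotate_tree(prof, tree)
  expect_equal(stringr::str_count(ann$newick, stringr::fixed("[&")), 11L)
  rt <- read_annotated_newick(ann$newick)
  expect_equal(sort(rt$annotations$node), sort(prof$node))
  merged <- merge(rt$annotations, prof, by = "node")
  expect_equal(merged$acceptor_score.x, merged$acceptor_score.y,
               tolerance = 1e-4)
  expect_equal(ape::Ntip(rt$tree), 6L)
  # single-leaf tree: its unlabelled root gets no profile, tip is annotated
  tr1 <- ape::read.tree(text = "(l1);")
  expect_warning(ann1 <- annotate_tree(prof, tr1), "no profile")
  expect_equal(stringr::str_count(ann1$newick, stringr::fixed("[&")), 1L)
  expect_warning(annotate_tree(prof[prof$node != "Y", ], tree),
                 "no profile")
})
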
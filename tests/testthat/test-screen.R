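# Hand-built two-member fixture: identical 12-codon exons except that the
# weak member carries GAAGAA (E E) at codons 5-6 where the strong member has
# TTTGAA (F E): one nonsynonymous difference inside the planted enhancer.
fixture_pair <- function(weak_acceptor = TRUE) {
  models <- ss_test_models()
  cutoffs <- c(3, 6)
  exon_w <- "ATGGCCAAACCCGAAGAATGGTACCTGGTGACCGGG"
  exon_s <- "ATGGCCAAACCCTTTGAATGGTACCTGGTGACCGGG"
  mk <- function(id, exon, strength) {
    acc <- splicescreen:::sample_site_flank(
      models$acceptor, strength, substr(exon, 1, 3), cutoffs
    )
    don <- splicescreen:::sample_site_flank(
      models$donor, "strong", substr(exon, nchar(exon) - 2, nchar(exon)),
      cutoffs
    )
    exon_record(id, exon,
                upstream_flank = paste0("TTTTTTTTTT", acc),
                downstream_flank = paste0(don, "TTTTTTTTTT"))
  }
  withr::with_seed(404, list(
    weak = mk("w", exon_w, if (weak_acceptor) "weak" else "strong"),
    strong = mk("s", exon_s, "strong")
  ))
}

test_that("hits project onto alignment columns through gaps", {
  a <- exon_record("a", "ATGGAAGCCAAATGGTTTGAA")
  b <- exon_record("b", "ATGGAAGCCTGGTTTGAA")
  al <- align_pair(a, b)
  # gapless member: identity mapping, codons 3-4 for nt [6,12)
  h <- tibble::tibble(seq_id = "a", start = 6L, end = 12L,
                      motif_name = "x", score = 0, kind = "ESE_HEX",
                      set_name = "x")
  ph <- project_hits(al, h, "a")
  expect_equal(ph$col_start, 3L)
  expect_equal(ph$col_end, 4L)
  expect_equal(ph$nt_col_start, 6L)
  expect_equal(ph$nt_col_end, 12L)
  # member with an upstream deletion: interval shifts by the gap width
  h_b <- tibble::tibble(seq_id = "b", start = 9L, end = 15L,
                        motif_name = "x", score = 0, kind = "ESE_HEX",
                        set_name = "x")
  ph_b <- project_hits(al, h_b, "b")
  # b's codons 4-5 (W, F) sit in columns 5-6, after the 1-column gap
  expect_equal(ph_b$col_start, 5L)
  expect_equal(ph_b$col_end, 6L)
  # a hit abutting the gap in the OTHER member keeps its gap column inside
  expect_true(ph_b$col_end - ph_b$col_start >= 1L)
  expect_error(project_hits(al, dplyr::mutate(h, end = 1000L), "a"),
               "outside")
})

test_that("screening identical exons yields no candidates", {
  models <- ss_test_models()
  a <- fixture_pair()$weak
  b <- a
  b$seq_id <- "b"
  expect_equal(nrow(screen_pair(a, b, models, plant_config())), 0L)
})

test_that("engineered weak+enhancer vs strong-ablated pair yields one candidate", {
  models <- ss_test_models()
  fx <- fixture_pair(weak_acceptor = TRUE)
  rep <- screen_pair(fx$weak, fx$strong, models, plant_config())
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$weak_member, "w")
  expect_equal(rep$strong_member, "s")
  expect_equal(rep$site_type, "acceptor")
  hit <- rep$ese_hits[[1]]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif_name, "GAAGAA")
  expect_equal(hit$start, 12L)   # codon 5, 0-based nt 12
  d <- rep$diffs[[1]]
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "nonsynonymous")
  expect_equal(d$column, 5L)
  expect_equal(c(d$aa_i, d$aa_j), c("E", "F"))
  # report invariants
  expect_gte(rep$delta, plant_config()$min_delta)
})

test_that("no candidate is reported when both acceptors are strong", {
  models <- ss_test_models()
  fx <- fixture_pair(weak_acceptor = FALSE)
  expect_equal(nrow(screen_pair(fx$weak, fx$strong, models, plant_config())),
               0L)
})

test_that("enhancer presence in the strong member vetoes the hit per set", {
  models <- ss_test_models()
  fx <- fixture_pair(weak_acceptor = TRUE)
  # a second set member that the strong exon retains at the same columns:
  # same-set presence must veto, even though the exact hexamer differs
  cfg <- screen_config(
    ese_hexsets = list(hexamer_set("plant", c("GAAGAA", "TTTGAA"))),
    site_of_interest = "acceptor"
  )
  expect_equal(nrow(screen_pair(fx$weak, fx$strong, models, cfg)), 0L)
})

test_that("adjacency window controls how far a difference may sit", {
  models <- ss_test_models()
  # enhancer at codons 5-6, nonsynonymous difference at codon 8 (K vs E):
  # distance 1 codon from the span end
  exon_w <- "ATGGCCAAACCCGAAGAATGGAAACTGGTGACCGGG"
  exon_s <- "ATGGCCAAACCCGACGAATGGGAACTGGTGACCGGG"
  # strong member: GAC GAA at 5-6 ('D E', hexamer ablated), GAA at 8
  mk <- function(id, exon, strength) {
    withr::with_seed(405, {
      acc <- splicescreen:::sample_site_flank(
        models$acceptor, strength, substr(exon, 1, 3), c(3, 6)
      )
      don <- splicescreen:::sample_site_flank(
        models$donor, "strong", substr(exon, nchar(exon) - 2, nchar(exon)),
        c(3, 6)
      )
      exon_record(id, exon, upstream_flank = paste0("AAAAAAAAAA", acc),
                  downstream_flank = paste0(don, "AAAAAAAAAA"))
    })
  }
  w <- mk("w", exon_w, "weak")
  s <- mk("s", exon_s, "strong")
  base <- list(hexamer_set("plant", "GAAGAA"))
  # diffs: codon 5 D>E is near the span anyway; make sure window-0 vs
  # window-2 behave consistently for the codon-8 diff
  cfg0 <- screen_config(ese_hexsets = base, adjacency_window = 0,
                        site_of_interest = "acceptor")
  cfg2 <- screen_config(ese_hexsets = base, adjacency_window = 2,
                        site_of_interest = "acceptor")
  r0 <- screen_pair(w, s, models, cfg0)
  r2 <- screen_pair(w, s, models, cfg2)
  expect_equal(nrow(r2), 1L)
  # window 2 additionally captures the codon-8 difference
  expect_true(8L %in% r2$diffs[[1]]$column)
  if (nrow(r0) > 0) {
    expect_false(8L %in% r0$diffs[[1]]$column)
  }
})

test_that("screen_family equals screen_pair on two records and scales up", {
  models <- ss_test_models()
  fx <- fixture_pair(weak_acceptor = TRUE)
  fam2 <- screen_family(list(fx$weak, fx$strong), models, plant_config())
  pair <- screen_pair(fx$weak, fx$strong, models, plant_config())
  expect_equal(fam2$weak_member, pair$weak_member)
  expect_equal(fam2$ese_hits, pair$ese_hits)
  expect_error(screen_family(list(fx$weak), models, plant_config()),
               "at least 2")
})

test_that("a family of identical records reports nothing", {
  models <- ss_test_models()
  a <- fixture_pair()$strong
  recs <- lapply(c("x", "y", "z"), function(id) {
    r <- a
    r$seq_id <- id
    r
  })
  expect_equal(nrow(screen_family(recs, models, plant_config())), 0L)
})

test_that("ALP-like 4-member family yields 3 reports against the strong member", {
  models <- ss_test_models()
  fam <- sim_paralog_family(
    seed = 907, n_members = 4,
    planted = tibble::tibble(member = c("m1", "m2", "m3"),
                             hexamer = "GAAGAA", codon = 10L),
    acceptor_strengths = c(m1 = "weak", m2 = "weak", m3 = "weak"),
    models = models
  )
  rep <- screen_family(unname(fam$records), models, plant_config())
  expect_equal(nrow(rep), 3L)
  expect_true(all(rep$strong_member == "m4"))
  expect_setequal(rep$weak_member, c("m1", "m2", "m3"))
})

test_that("flatten_reports serialises spans 1-based", {
  models <- ss_test_models()
  fx <- fixture_pair(weak_acceptor = TRUE)
  rep <- screen_pair(fx$weak, fx$strong, models, plant_config())
  flat <- flatten_reports(rep)
  expect_equal(flat$ese_spans, "GAAGAA:13-18")
  expect_match(flat$diff_list, "col5:E>F")
})
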
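mk_record <- function(id, dpph, abts, spfi, lc, ratio) {
  data.frame(isolate_id = id, rsc_dpph = dpph, rsc_abts = abts, spfi = spfi,
             lambda_c_nm = lc, uva_uvb_ratio = ratio, stringsAsFactors = FALSE)
}

test_that("selection filters apply the cutoffs conjunctively", {
  recs <- rbind(
    mk_record("pass", 55, 60, 5, 380, 0.9),
    mk_record("failABTS", 55, 45, 5, 380, 0.9),
    mk_record("failSPFi", 55, 60, 1.5, 380, 0.9),
    mk_record("failLC", 55, 60, 5, 368, 0.9),
    mk_record("failRatio", 55, 60, 5, 380, 0.65))
  out <- select_candidates(recs)
  expect_equal(out$isolate_id[out$selected], "pass")
  expect_false(out$pass_abts[out$isolate_id == "failABTS"])
  audit <- attr(out, "audit")
  expect_equal(nrow(audit), 5 * 5)
  expect_true(all(audit$pass[audit$isolate_id == "pass"]))
})

test_that("records with missing metrics get incomplete status, not dropped", {
  recs <- rbind(mk_record("ok", 60, 60, 5, 380, 0.9),
                mk_record("gap", 60, NA, 5, 380, 0.9))
  out <- select_candidates(recs)
  expect_equal(out$status[out$isolate_id == "gap"], "incomplete")
  expect_equal(nrow(out), 2L)
})

test_that("selection is monotone under threshold relaxation", {
  set.seed(31)
  recs <- mk_record(sprintf("I%02d", 1:30), runif(30, 30, 70),
                    runif(30, 30, 70), runif(30, 0, 8),
                    runif(30, 350, 395), runif(30, 0.3, 1.2))
  strict <- select_candidates(recs, run_config())
  for (arg in list(list(rsc_cutoff_pct = 40), list(spfi_cutoff = 1),
                   list(lambda_c_cutoff_nm = 360), list(uva_uvb_cutoff = 0.5))) {
    relaxed <- select_candidates(recs, do.call(run_config, arg))
    expect_true(all(strict$isolate_id[strict$selected] %in%
                      relaxed$isolate_id[relaxed$selected]))
  }
})

test_that("triangle score closed forms, symmetry, homogeneity", {
  expect_equal(triangle_score(0, 0, 0), 0)
  expect_equal(triangle_score(1, 1, 1), sqrt(3) / 4 * 3)
  expect_equal(triangle_score(50, 60, 70), sqrt(3) / 4 * (3000 + 4200 + 3500))
  # permutation invariance and degree-2 homogeneity
  set.seed(5)
  for (i in 1:10) {
    v <- runif(3, 0, 100)
    p <- sample(3)
    expect_equal(triangle_score(v[1], v[2], v[3]),
                 triangle_score(v[p[1]], v[p[2]], v[p[3]]))
    k <- runif(1, 0.1, 4)
    expect_equal(triangle_score(k * v[1], k * v[2], k * v[3]),
                 k^2 * triangle_score(v[1], v[2], v[3]), tolerance = 1e-9)
  }
  expect_error(triangle_score(-1, 10, 10), "nonnegative")
})

test_that("ranking is deterministic, total, and recovers injected order", {
  recs <- data.frame(isolate_id = c("a", "b", "c"), score = c(3, 1, 2))
  expect_equal(rank_records(recs)$isolate_id, c("a", "c", "b"))
  # exact tie -> lexicographic
  tie <- data.frame(isolate_id = c("z", "m"), score = c(2, 2))
  expect_equal(rank_records(tie)$isolate_id, c("m", "z"))
  # injected scores on a 10-record panel; shuffled input gives same output
  set.seed(13)
  inj <- data.frame(isolate_id = sprintf("G%02d", 1:10),
                    score = sample(seq(10, 100, by = 10)))
  want <- inj$isolate_id[order(-inj$score)]
  for (i in 1:3) {
    shuf <- inj[sample(nrow(inj)), , drop = FALSE]
    expect_equal(rank_records(shuf)$isolate_id, want)
  }
})

test_that("pearson_with_p matches the cor.test oracle", {
  x <- 1:10
  exact <- pearson_with_p(x, 2 * x)
  expect_equal(exact$r, 1)
  expect_lt(exact$p, 1e-12)
  # orthogonal construction -> r = 0
  orth <- pearson_with_p(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(orth$r, 0)
  # fixed-seed bivariate normal vs the stats::cor.test oracle
  set.seed(32)
  n <- 32
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  got <- pearson_with_p(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_gt(got$r, 0.2); expect_lt(got$r, 0.75)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero-variance")
})

test_that("screen_panel normalizes SPFi to the reference filter when set", {
  recs <- rbind(mk_record("hi", 70, 70, 8, 385, 1.0),
                mk_record("lo", 60, 60, 4, 380, 0.9))
  out <- screen_panel(recs, run_config(spfi_reference = 10))
  expect_equal(out$ranking$spfi_pct, c(80, 40))
  expect_equal(out$ranking$isolate_id, c("hi", "lo"))
  expect_equal(out$ranking$rank, 1:2)
})
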
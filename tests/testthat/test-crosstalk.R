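test_that("align_samples restricts both tissues to shared samples in order", {
  set.seed(1)
  o <- matrix(rnorm(10 * 50), 10, dimnames = list(paste0("o", 1:10), paste0("s", 1:50)))
  t1 <- matrix(rnorm(8 * 50), 8, dimnames = list(paste0("t", 1:8), paste0("s", 1:50)))
  suppressMessages(al <- align_samples(o, t1))
  expect_identical(al$origin, o)
  expect_identical(al$target, t1)

  t2 <- t1[, paste0("s", 11:50)]
  suppressMessages(al2 <- align_samples(o, t2))
  expect_equal(al2$n_shared, 40L)
  expect_identical(colnames(al2$origin), colnames(al2$target))
  expect_identical(sort(colnames(al2$origin)), sort(paste0("s", 11:50)))

  t3 <- t1; colnames(t3) <- paste0("x", 1:50)
  expect_error(suppressMessages(align_samples(o, t3)), "shared samples")
})

test_that("S_sec hits the cap under perfect coupling and the analytic null mean otherwise", {
  set.seed(2)
  n <- 50
  x <- rnorm(n)
  origin <- matrix(x, 1, dimnames = list("med", sprintf("s%02d", 1:n)))
  # every target row a positive affine copy of x -> every p = 0 -> cap
  target <- matrix(rep(x, each = 20), 20,
                   dimnames = list(paste0("t", 1:20), colnames(origin))) *
    runif(20, 0.5, 2) + rnorm(20)
  sc <- ssec_score("med", origin, target)
  expect_equal(sc$s_sec, 300) # -log10(1e-300)
  expect_equal(attr(sc, "cap"), 300)
  expect_error(ssec_score("absent", origin, target), "absent")

  # independent targets: E[-log10 U] = 1/ln(10) ~ 0.434
  pd <- generate_panel(panel_spec(n_samples = 100L, n_origin_genes = 5L,
                                  n_target_genes = 2000L, n_secreted = 2L,
                                  planted_mediators = list(), seed = 3))
  sc0 <- ssec_score("OG0001", pd$origin, pd$target)
  expect_equal(sc0$n_target_genes, 2000L)
  expect_lt(abs(sc0$s_sec - 1 / log(10)), 0.05)
})

test_that("planted mediator outscores decoys and ranks first", {
  pd <- small_panel(seed = 4)
  suppressMessages(rk <- rank_mediators(pd$origin, pd$target, pd$secretome))
  expect_identical(rk$origin_gene[1], "OG0001")
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_gt(rk$s_sec[1], median(rk$s_sec))
  # single-gene secretome
  suppressMessages(one <- rank_mediators(pd$origin, pd$target, "OG0002"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$rank, 1L)
  expect_error(suppressMessages(
    rank_mediators(pd$origin, pd$target, c("NOPE1", "NOPE2"))),
    "no secreted genes")
})

test_that("tied scores break ties by gene symbol, deterministically", {
  pd <- small_panel(seed = 5, coupled = FALSE)
  origin <- pd$origin
  origin["OG0009", ] <- origin["OG0002", ] # identical expression -> tied score
  suppressMessages(rk <- rank_mediators(origin, pd$target,
                                        c("OG0009", "OG0002")))
  expect_identical(rk$origin_gene, c("OG0002", "OG0009"))
  suppressMessages(rk2 <- rank_mediators(origin, pd$target,
                                         c("OG0002", "OG0009")))
  expect_identical(rk, rk2)
})

test_that("zero-MAD secreted genes are skipped with a tally", {
  pd <- small_panel(seed = 6, coupled = FALSE)
  origin <- pd$origin
  origin["OG0003", ] <- 1.5
  sec <- c("OG0002", "OG0003", "OG0004")
  suppressMessages(rk <- rank_mediators(origin, pd$target, sec))
  expect_false("OG0003" %in% rk$origin_gene)
  expect_equal(unname(attr(rk, "skipped_origin")["zero_mad"]), 1L)
})

test_that("permutation null is seeded, bounded, and detects planted coupling", {
  pd <- small_panel(seed = 7)
  expect_error(ssec_permutation_null("OG0001", pd$origin, pd$target,
                                     n_perm = 50), ">= 100")
  pn <- ssec_permutation_null("OG0001", pd$origin, pd$target,
                              n_perm = 199, seed = 9)
  expect_length(pn$null, 199)
  expect_gte(pn$perm_p, 1 / 200)
  expect_lte(pn$perm_p, 1)
  # strong planted coupling: observed should beat every null draw
  expect_equal(pn$perm_p, 1 / 200)
  pn2 <- ssec_permutation_null("OG0001", pd$origin, pd$target,
                               n_perm = 199, seed = 9)
  expect_identical(pn$null, pn2$null)
})

test_that("empirical p follows the pseudocount convention at both boundaries", {
  # the pseudocount (1 + exceedances) / (1 + n_perm) never reaches 0,
  # and equals 1 when every null draw is at least the observed score
  pd <- small_panel(seed = 8, coupled = FALSE)
  origin <- pd$origin
  # a decoy gene on an uncoupled panel: p must be well inside (0, 1]
  pn <- ssec_permutation_null("OG0005", origin, pd$target,
                              n_perm = 199, seed = 1)
  expect_equal(pn$perm_p, (1 + sum(pn$null >= pn$observed)) / 200)
})

test_that("S_sec permutation p-values are calibrated on uncoupled panels", {
  n_datasets <- 200L
  tests <- 0L
  rejections <- 0L
  for (s in seq_len(n_datasets)) {
    pd <- generate_panel(panel_spec(n_samples = 50L, n_origin_genes = 4L,
                                    planted_mediators = list(),
                                    n_target_genes = 120L, n_secreted = 2L,
                                    seed = 1000L + s))
    for (g in c("OG0001", "OG0002")) {
      pn <- ssec_permutation_null(g, pd$origin, pd$target,
                                  n_perm = 199, seed = s + (g == "OG0002"))
      tests <- tests + 1L
      rejections <- rejections + (pn$perm_p <= 0.05)
    }
  }
  rate <- rejections / tests
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("BH adjustment matches hand cases, the naive oracle, and p.adjust", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(10)
  for (k in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_identical(q, oracle_bh(p))
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    # step-up outputs are monotone in the sorted order and bounded by 1
    expect_true(all(diff(q[order(p)]) >= 0))
    expect_true(all(q <= 1 & q >= p * length(p) / length(p) * 0))
  }
})

test_that("gene-centric profile finds the coupled tissue and honours the q cutoff", {
  hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    pd <- small_panel(seed = 100 + s)
    # tissue A carries the planted coupling; B is independent noise
    noise <- matrix(rnorm(150 * ncol(pd$origin)), 150,
                    dimnames = list(sprintf("NG%04d", 1:150), colnames(pd$origin)))
    prof <- gene_centric_profile("OG0001", pd$origin,
                                 list(coupled = pd$target, noise = noise))
    expect_setequal(prof$profile$tissue, c("coupled", "noise"))
    expect_true(all(prof$profile$q >= prof$profile$p * 0)) # q well-formed
    counts <- prof$summary$n_significant
    expect_identical(counts,
                     vapply(split(prof$profile, prof$profile$tissue)[prof$summary$tissue],
                            function(d) sum(d$q < prof$q_threshold), integer(1),
                            USE.NAMES = FALSE))
    hits <- hits + (prof$summary$tissue[1] == "coupled")
  }
  expect_equal(hits, n_seeds)
  # a tissue with too few shared samples is skipped; none left -> error
  pd <- small_panel(seed = 1)
  bad <- pd$target; colnames(bad) <- paste0("z", seq_len(ncol(bad)))
  expect_error(suppressMessages(
    gene_centric_profile("OG0001", pd$origin, list(bad = bad))),
    "sufficient sample overlap")
})
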
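test_that("component statistics hit their closed-form limits", {
  # identical populations: no differentiation, no diversity difference
  m <- rand_aln(4, 30, id = "g")
  same <- component_stats(m, m)
  expect_equal(unname(same["delta_div"]), 0)
  expect_lt(abs(same["fst_mol"]), 0.35)  # small-sample Phi noise around 0

  # complete fixation: Phi = 1, branch length at the clamp, delta 0 (both
  # populations internally monomorphic)
  w <- mk_aln(rep("AAAA", 4), "g"); d <- mk_aln(rep("TTTT", 4), "g")
  cs <- component_stats(w, d)
  expect_equal(unname(cs["fst_mol"]), 1)
  expect_equal(unname(cs["branch_len"]), -log(0.01))
  expect_equal(unname(cs["delta_div"]), 0)

  # pooled monomorphic fragments are excluded
  expect_null(component_stats(mk_aln(rep("AA", 3), "g"),
                              mk_aln(rep("AA", 3), "g")))

  # wild polymorphic, domesticated monomorphic, moderate divergence:
  # all three components positive
  w2 <- mk_aln(c("AAAA", "AATA", "AAAA", "AATA"), "g")
  d2 <- mk_aln(rep("TTAA", 4), "g")
  cs2 <- component_stats(w2, d2)
  expect_true(all(cs2 > 0))

  # branch length closed form at FST 0.5
  expect_equal(-log(1 - 0.5), log(2))
})

test_that("selection index is a sum of z-scores with sd-zero silencing", {
  comp <- data.frame(fst_mol = c(1, 1), branch_len = c(1, 1),
                     delta_div = c(1, 1))
  expect_equal(as.numeric(selection_index(comp)), c(0, 0))

  comp2 <- data.frame(fst_mol = c(1, 3), branch_len = c(1, 3),
                      delta_div = c(1, 3))
  idx <- as.numeric(selection_index(comp2))
  expect_equal(idx[1], -idx[2])
  expect_equal(idx[2], 3 * (3 - 2) / sd(c(1, 3)))

  # location invariance
  comp3 <- comp2 + 10
  expect_equal(as.numeric(selection_index(comp3)), idx)
})

test_that("empirical p counts the exceeding fraction", {
  null <- 1:100
  expect_equal(empirical_p(200, null), 0)
  expect_equal(empirical_p(0, null), 1)
  expect_equal(empirical_p(50.5, null), 0.5)
  expect_equal(empirical_p(50.5, null, add_one = TRUE), 51 / 101)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("BH step-up matches the hand rule, p.adjust, and is monotone in alpha", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 4 * 0.04 / 3, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)

  set.seed(71)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    # flagged set never shrinks as alpha grows
    f1 <- q < 0.01; f2 <- q < 0.05; f3 <- q < 0.2
    expect_true(all(f1 <= f2) && all(f2 <= f3))
  }
})

test_that("null simulation is reproducible and records monomorphic replicates", {
  model <- demographic_model(1)
  pri <- fixed_priors(model$params)
  a <- simulate_null(model, pri, n_sims = 40, lengths = c(200, 400),
                     mu_prior = list(dist = "fixed", value = 1e-8), seed = 11)
  b <- simulate_null(model, pri, n_sims = 40, lengths = c(200, 400),
                     mu_prior = list(dist = "fixed", value = 1e-8), seed = 11)
  expect_identical(a$components, b$components)
  expect_equal(a$n_sims, 40L)
  expect_true(a$n_polymorphic <= 40L)

  # degenerate priors with a tiny mutation rate: everything monomorphic
  tiny <- simulate_null(model, pri, n_sims = 5, lengths = 100,
                        mu_prior = list(dist = "fixed", value = 1e-15),
                        seed = 2)
  expect_equal(tiny$n_polymorphic, 0L)
})

test_that("single-population reduction reproduces the Watterson expectation", {
  # collapse structure: no bottleneck, equal sizes, no migration
  p <- default_demography_params()
  p$I_MD <- 100; p$N_MD <- p$N_MWANC; p$N_MW <- p$N_MWANC
  p$M_WD <- 0; p$M_DW <- 0
  model <- demographic_model(1, p)
  set.seed(3)
  n <- 12; L <- 200; mu <- 1e-8
  S <- replicate(600, ncol(sim_fragment(model, n, 0, L, mu)))
  theta_site <- 2 * p$N_MWANC * mu
  a_n <- sum(1 / seq_len(n - 1))
  expected <- theta_site * a_n * L
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("a severe domestication bottleneck biases delta_div positive", {
  model <- demographic_model(1)  # includes the calibrated bottleneck
  set.seed(5)
  deltas <- replicate(300, {
    X <- sim_fragment(model, 10, 10, 400, 1e-8)
    cs <- component_stats(X[1:10, , drop = FALSE], X[11:20, , drop = FALSE])
    if (is.null(cs)) NA else cs[["delta_div"]]
  })
  expect_gt(mean(deltas, na.rm = TRUE), 0)
})

test_that("scan runs under both demographic models and reports structure", {
  cfg <- generator_config(n_loci = 6, seed = 42)
  ds <- generate_dataset(cfg)
  s1 <- scan_selection(ds, demographic_model(1), n_sims = 150, seed = 9)
  s2 <- scan_selection(ds, demographic_model(2), n_sims = 150, seed = 9)
  expect_equal(s1$model_id, 1L)
  expect_equal(s2$model_id, 2L)
  for (s in list(s1, s2)) {
    expect_true(all(s$fragments$q_bh >= 0 & s$fragments$q_bh <= 1))
    expect_true(all(s$fragments$p_raw >= 0 & s$fragments$p_raw <= 1))
    expect_true(all(s$fragments$class %in% c("exonic", "intronic")))
    expect_setequal(unique(s$genes$flagged), unique(s$genes$min_q < 0.05))
  }
  # byte-level determinism of the full scan under one seed
  s1b <- scan_selection(ds, demographic_model(1), n_sims = 150, seed = 9)
  expect_identical(s1$fragments, s1b$fragments)
})

test_that("demography configs round-trip and priors sample within bounds", {
  model <- demographic_model(2, list(N_MW = 300000))
  f <- tempfile(fileext = ".json")
  write_demography_config(model, f, priors = list(
    I_MD = list(dist = "logunif", min = 0.1, max = 10)))
  back <- read_demography_config(f)
  expect_equal(back$model$model_id, 2L)
  expect_equal(back$model$params$N_MW, 300000)

  set.seed(1)
  pri <- default_priors(1)
  for (i in 1:20) {
    s <- sample_model_params(pri)
    expect_null(beanscan:::validate_demography_params(s$params))
  }
  expect_error(demographic_model(1, list(T_EMD = 9000)), "T_EMD")
})
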
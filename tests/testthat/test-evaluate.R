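toy_agg <- function(n = 10, p = 20, seed = 1, batches = 1) {
  set.seed(seed)
  ds <- lapply(seq_len(batches), function(b) {
    m <- toy_matrix(rexp(n * p) + 0.1, n, samples = paste0("b", b, "s", 1:n))
    rank_transform(raw_dataset(m, paste0("b", b)))
  })
  quiet(aggregate_ranked(ds))
}

test_that("within-design masks hold-out features in hold-out samples only", {
  agg <- toy_agg(10, 20)
  plan <- make_mask_within(agg, frac_samples = 0.5, frac_features = 0.1, seed = 3)
  expect_identical(length(plan$held_samples), 5L)
  expect_identical(length(plan$held_features), 2L)
  expect_identical(sum(plan$mask), 10L)  # 5 samples x 2 features
  expect_true(all(plan$mask[plan$held_samples, plan$held_features]))
  # masked cells are a subset of observed cells
  expect_true(all(agg$observed[plan$mask]))
  # determinism
  expect_identical(make_mask_within(agg, seed = 3)$mask, plan$mask)
  expect_error(make_mask_within(agg, frac_features = 1.0), "\\(0, 1\\)")
  expect_error(make_mask_within(agg, frac_features = 0.001), "zero")
})

test_that("across-design masks selected shared features in every target sample", {
  sets <- list(paste0("f", 1:30), paste0("f", 1:30))
  ds <- lapply(1:2, function(b) {
    set.seed(b)
    rank_transform(raw_dataset(
      toy_matrix(rexp(120) + 0.1, 4, samples = paste0("b", b, "s", 1:4),
                 features = sets[[b]]), paste0("b", b)))
  })
  agg <- quiet(aggregate_ranked(ds))
  plan <- make_mask_across(agg, target = "b2", frac_features = 0.1, seed = 5)
  expect_identical(length(plan$held_features), 3L)  # 10% of 30 shared
  expect_true(all(plan$mask[agg$batch == "b2", plan$held_features]))
  # non-target batches untouched
  expect_false(any(plan$mask[agg$batch == "b1", ]))

  # features unique to the target are excluded from the candidate pool
  ds2 <- list(ds[[1]],
              rank_transform(raw_dataset(
                toy_matrix(rexp(124) + 0.1, 4, samples = paste0("c", 1:4),
                           features = c(paste0("f", 1:30), "only_here")), "b2")))
  agg2 <- quiet(aggregate_ranked(ds2))
  for (s in 1:10) {
    expect_false("only_here" %in%
                   make_mask_across(agg2, "b2", 0.2, seed = s)$held_features)
  }
  expect_error(make_mask_across(agg2, "b2", candidates = "only_here",
                                frac_features = 0.9), "nowhere")
})

test_that("mode-design masks one mode in half the samples and scores single-mode features", {
  fx <- make_fixture("tiny-mode", seed = 6)
  agg <- quiet(aggregate_ranked(list(rank_transform(normalize_dataset(fx$datasets[[1]])))))
  plan <- make_mask_mode(agg, modes = fx$modes, masked_mode = "neg",
                         frac_samples = 0.5, seed = 7,
                         metabolite_of = fx$metabolite_of)
  expect_identical(length(plan$held_samples), 8L)
  neg_feats <- names(fx$modes)[fx$modes == "neg"]
  expect_setequal(colnames(agg$values)[colSums(plan$mask) > 0], neg_feats)
  # evaluation set: single-mode negative features only
  expect_setequal(plan$held_features,
                  intersect(neg_feats, names(fx$metabolite_of)[grepl("solo", fx$metabolite_of)]))
  expect_identical(make_mask_mode(agg, fx$modes, "neg", seed = 7,
                                  metabolite_of = fx$metabolite_of)$mask, plan$mask)
  expect_error(make_mask_mode(agg, fx$modes[-1], metabolite_of = fx$metabolite_of),
               "without a mode")
  allneg <- setNames(rep("neg", ncol(agg$values)), colnames(agg$values))
  expect_error(make_mask_mode(agg, allneg, "neg"), "every feature")
})

test_that("trial scoring matches identity, anti-identity, and the brute-force oracle", {
  agg <- toy_agg(12, 6)
  plan <- make_mask_within(agg, 0.5, 0.2, seed = 2)
  truth <- agg

  perfect <- structure(list(values = agg$values), class = "mirth_imputed")
  sc <- score_trial(truth, agg$values, plan)
  expect_true(all(sc$rho[sc$scored] == 1))

  flipped <- agg$values
  for (f in plan$held_features) {
    cells <- plan$mask[, f]
    flipped[cells, f] <- 1 - flipped[cells, f]
  }
  sc2 <- score_trial(truth, flipped, plan)
  expect_true(all(sc2$rho[sc2$scored] == -1))

  set.seed(13)
  noisy <- agg$values + matrix(rnorm(length(agg$values), 0, 0.3), nrow(agg$values))
  sc3 <- score_trial(truth, noisy, plan)
  for (i in which(sc3$scored)) {
    f <- sc3$feature[i]
    cells <- plan$mask[, f]
    expect_equal(sc3$rho[i], oracle_spearman(agg$values[cells, f], noisy[cells, f]),
                 tolerance = 1e-12)
  }
  # observed cells never contribute: perturbing them leaves scores unchanged
  perturbed <- noisy
  perturbed[!plan$mask] <- runif(sum(!plan$mask))
  expect_equal(score_trial(truth, perturbed, plan)$rho, sc3$rho)
})

test_that("too-few or zero-variance masked samples leave a feature unscored", {
  agg <- toy_agg(4, 10)
  plan <- make_mask_within(agg, frac_samples = 0.5, frac_features = 0.2, seed = 1)
  sc <- score_trial(agg, agg$values, plan)  # only 2 masked samples per feature
  expect_true(all(!sc$scored))
  expect_true(all(is.na(sc$rho)))
})

test_that("Fisher-z summarization honours its identities and monotonicity", {
  expect_equal(summarize_rho(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(summarize_rho(0.73), 0.73)
  expect_equal(summarize_rho(c(-0.3, 0, 0.3)), 0)
  expect_error(summarize_rho(numeric(0)), "no correlations")
  expect_error(summarize_rho(1.2), "\\[-1, 1\\]")
  expect_warning(s <- summarize_rho(c(1, 0.5, 0.2)), "clipped")
  expect_true(s <= 1)
  # increasing any input never decreases the summary
  set.seed(3)
  for (i in 1:20) {
    r <- runif(7, -0.9, 0.9)
    j <- sample(7, 1)
    r2 <- r
    r2[j] <- min(r[j] + runif(1, 0, 0.5), 0.99)
    expect_gte(summarize_rho(r2), summarize_rho(r))
  }
})

test_that("BH adjustment reproduces the hand-computed step-up and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("well-predicted calls use a strict 90% trial threshold", {
  scores <- tibble::tibble(
    feature = rep(c("hit", "edge"), each = 20),
    rho = rep(0.8, 40),
    q = c(rep(0.01, 19), 0.5,            # 19/20 = 95% significant
          rep(0.01, 18), 0.5, 0.5)       # 18/20 = 90% exactly
  )
  flags <- classify_well_predicted(scores)
  expect_true(flags$well_predicted[flags$feature == "hit"])
  expect_false(flags$well_predicted[flags$feature == "edge"])  # 90% is not > 90%
  # negative correlations never count as significant
  neg <- tibble::tibble(feature = "x", rho = rep(-0.9, 10), q = rep(1e-5, 10))
  expect_false(classify_well_predicted(neg)$well_predicted)
})

test_that("reproducibility requires >= 4 batches and >= 3/4 of them well-predicted", {
  flags <- tibble::tibble(
    feature = c(rep("three", 3), rep("four", 4), rep("half", 4)),
    batch = c(paste0("b", 1:3), paste0("b", 1:4), paste0("b", 1:4)),
    well_predicted = c(TRUE, TRUE, TRUE,          # 3/3 but only 3 batches
                       TRUE, TRUE, TRUE, FALSE,   # 3/4 of 4 batches
                       TRUE, TRUE, FALSE, FALSE)  # 2/4
  )
  rep_flags <- classify_reproducible(flags)
  get <- function(f) rep_flags$reproducibly_well_predicted[rep_flags$feature == f]
  expect_false(get("three"))
  expect_true(get("four"))
  expect_false(get("half"))
})

test_that("embedding enrichment matches the hypergeometric extreme and handles cutoffs", {
  H <- rbind(dim1 = c(a1 = 0.9, a2 = 0.8, a3 = 0.7, b1 = 0.01, b2 = 0.05,
                      b3 = 0.02, b4 = 0.1, b5 = 0.05, b6 = 0.01, b7 = 0.1))
  ann <- tibble::tibble(feature = c(paste0("a", 1:3), paste0("b", 1:7)),
                        pathway = c(rep("A", 3), rep("B", 7)))
  res <- enrichment_by_dimension(structure(list(H = H, k = 1), class = "mirth_nmf"),
                                 ann, cutoff = 0.2)
  # above-cutoff set is exactly pathway A: its test is the most extreme
  expect_identical(res$pathway[which.min(res$p)], "A")
  # (5,0;0,5) table: two-sided Fisher p = 2/choose(10,5) = 1/126
  tbl_p <- enrichment_by_dimension(
    rbind(c(setNames(rep(0.9, 5), paste0("x", 1:5)),
            setNames(rep(0.01, 5), paste0("y", 1:5)))),
    tibble::tibble(feature = c(paste0("x", 1:5), paste0("y", 1:5)),
                   pathway = rep(c("X", "Y"), each = 5)), cutoff = 0.2)
  expect_equal(min(tbl_p$p), 2 / choose(10, 5), tolerance = 1e-12)
  # cutoff above all weights: no tests at all
  none <- enrichment_by_dimension(H, ann, cutoff = 2)
  expect_identical(nrow(none), 0L)
})

test_that("the benchmark harness assembles per-trial BH-corrected scores", {
  fx <- make_fixture("tiny-across", seed = 9)
  bench <- quiet(run_benchmark(fx$datasets, design = "across", k = 2, trials = 3,
                               seed = 4, target = "batch2"))
  sc <- tidy(bench)
  expect_identical(sort(unique(sc$trial)), 1:3)
  # q-values are monotone in p within each trial
  for (t in unique(sc$trial)) {
    st <- sc[sc$trial == t & sc$scored, ]
    expect_true(all(diff(st$q[order(st$p)]) >= -1e-12))
    expect_equal(st$q, bh_adjust(st$p))
  }
  g <- glance(bench)
  expect_true(g$rho_summary >= -1 && g$rho_summary <= 1)
  expect_s3_class(autoplot(bench), "ggplot")
})
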
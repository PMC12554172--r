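make_densitometry <- function() {
  tibble::tibble(
    condition = "WT",
    timepoint_min = rep(c(0, 30), each = 2),
    replicate = rep(1:2, 2),
    band_intensity = c(800, 820, 400, 410),
    loading_intensity = c(400, 410, 400, 410)
  )
}

test_that("densitometry normalization anchors the reference at 100%", {
  out <- normalize_densitometry(make_densitometry())
  expect_equal(out$norm_pct[out$timepoint_min == 0], c(100, 100))
  expect_equal(out$norm_pct[out$timepoint_min == 30], c(50, 50))

  # per-replicate global intensity rescaling cancels exactly
  scaled <- make_densitometry()
  r2 <- scaled$replicate == 2
  scaled$band_intensity[r2] <- scaled$band_intensity[r2] * 10
  scaled$loading_intensity[r2] <- scaled$loading_intensity[r2] * 10
  expect_equal(
    normalize_densitometry(scaled)$norm_pct,
    normalize_densitometry(make_densitometry())$norm_pct
  )

  bad <- make_densitometry()
  bad$loading_intensity[3] <- 0
  expect_error(normalize_densitometry(bad),
    regexp = "3",
    class = "degronmap_error_loading"
  )
})

test_that("co-IP association is input-normalized and scaled to wild type", {
  tab <- tibble::tibble(
    condition = c("WT", "WT", "C13S", "C13S", "IgG"),
    replicate = c(1, 2, 1, 2, 1),
    ip_intensity = c(50, 52, 26, 25, 0.5),
    input_intensity = c(100, 104, 104, 100, 100)
  )
  out <- coip_association(tab)
  expect_equal(mean(out$pct_of_wt[out$condition == "WT"]), 100)
  expect_equal(out$pct_of_wt[out$condition == "C13S"], c(50, 50))
  expect_true(out$is_control[out$condition == "IgG"])
  expect_lt(out$pct_of_wt[out$condition == "IgG"], 2)

  expect_error(coip_association(dplyr::filter(tab, condition != "WT")),
    class = "degronmap_error_argument"
  )
})

test_that("noiseless decay fits are the identity on the half-life grid", {
  for (th in c(5, 10, 19.5, 33.5, 60)) {
    fit <- fit_decay(gen_chase(th))
    expect_equal(fit$t_half, th, tolerance = 1e-9)
    # nls on the raw scale agrees on clean data
    fit_nls <- fit_decay(gen_chase(th), method = "nls")
    expect_equal(fit_nls$t_half, th, tolerance = 1e-6)
  }
})

test_that("half-life estimator shows small median bias at 5% noise", {
  est <- vapply(1:200, function(i) {
    cfg <- generator_config(
      seed = i, noise_model = "multiplicative-lognormal", noise_scale = 0.05
    )
    fit_decay(gen_chase(19.5, config = cfg))$t_half
  }, numeric(1))
  expect_lt(abs(median(est) / 19.5 - 1), 0.03)
})

test_that("degenerate decay inputs are rejected or reported", {
  up <- tibble::tibble(
    timepoint_min = c(0, 30, 60), abundance_pct = c(100, 140, 180)
  )
  expect_error(fit_decay(up), class = "degronmap_error_no_decay")
  expect_error(
    fit_decay(tibble::tibble(
      timepoint_min = c(0, 10), abundance_pct = c(100, 50)
    )),
    class = "degronmap_error_fit"
  )
  # plateau option reports AIC for both models
  ch <- gen_chase(20, config = generator_config(
    seed = 2, noise_model = "multiplicative-lognormal", noise_scale = 0.05
  ))
  pf <- fit_decay(ch, model = "plateau")
  expect_named(pf$aic, c("single", "plateau"))
  expect_false(is.na(pf$plateau))
})

test_that("stabilization comparison flags planted interactions, matching TukeyHSD", {
  set.seed(9)
  d <- tidyr::expand_grid(
    genotype = c("WT", "C13S"), treatment = c("vehicle", "MG132"),
    replicate = 1:3
  ) |>
    dplyr::mutate(value = 100 * ifelse(
      genotype == "WT" & treatment == "MG132", 2, 1
    ) * exp(rnorm(dplyr::n(), 0, 0.05)))
  res <- compare_stabilization(d, "value", "genotype", "treatment")
  expect_true(res$anova$significant[res$anova$term == "interaction"])
  wt_pair <- grepl("WT:vehicle", res$pairwise$contrast) &
    grepl("WT:MG132", res$pairwise$contrast)
  expect_true(res$pairwise$significant[wt_pair])
  # only contrasts sharing a factor level are reported
  expect_equal(nrow(res$pairwise), 4)

  # oracle: stats::TukeyHSD on the interaction gives the same adjusted p
  fit <- aov(value ~ g * t, data = data.frame(
    value = d$value, g = factor(d$genotype), t = factor(d$treatment)
  ))
  hsd <- as.data.frame(TukeyHSD(fit, "g:t")$`g:t`)
  for (i in seq_len(nrow(res$pairwise))) {
    parts <- strsplit(res$pairwise$contrast[i], " - ")[[1]]
    key1 <- paste(parts[1], parts[2], sep = "-")
    key2 <- paste(parts[2], parts[1], sep = "-")
    row <- hsd[rownames(hsd) %in% c(key1, key2), ]
    expect_equal(res$pairwise$p_adj[i], row$`p adj`, tolerance = 1e-8)
  }
})

test_that("stabilization comparison handles degenerate designs", {
  # two groups only: falls back to Student's t test
  d2 <- tibble::tibble(
    genotype = rep("WT", 6),
    treatment = rep(c("vehicle", "MG132"), each = 3),
    value = c(100, 102, 98, 210, 190, 205)
  )
  res2 <- compare_stabilization(d2, "value", "genotype", "treatment")
  expect_equal(res2$method, "t-test")
  tt <- t.test(value ~ treatment, data = d2, var.equal = TRUE)
  expect_equal(res2$pairwise$p_adj, tt$p.value, tolerance = 1e-10)

  # empty cell rejected with its id
  d3 <- tibble::tibble(
    genotype = c("WT", "WT", "WT", "WT", "C13S", "C13S"),
    treatment = c("vehicle", "vehicle", "MG132", "MG132", "vehicle", "vehicle"),
    value = rnorm(6, 100)
  )
  expect_error(compare_stabilization(d3, "value", "genotype", "treatment"),
    class = "degronmap_error_design"
  )

  # null data: interaction flag rate stays near the nominal level
  set.seed(10)
  flags <- replicate(100, {
    dn <- tidyr::expand_grid(
      genotype = c("a", "b"), treatment = c("x", "y"), replicate = 1:3
    ) |>
      dplyr::mutate(value = rnorm(dplyr::n(), 100, 10))
    res <- compare_stabilization(dn, "value", "genotype", "treatment")
    res$anova$significant[res$anova$term == "interaction"]
  })
  expect_lte(mean(flags), 0.12)
})

test_that("stabilization Bonferroni adjustment scales the raw p-values", {
  set.seed(11)
  d <- tidyr::expand_grid(
    genotype = c("WT", "C13S"), treatment = c("vehicle", "MG132"),
    replicate = 1:3
  ) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 100, 8))
  tk <- compare_stabilization(d, "value", "genotype", "treatment")
  bf <- compare_stabilization(d, "value", "genotype", "treatment",
    adjust = "bonferroni"
  )
  expect_equal(bf$pairwise$contrast, tk$pairwise$contrast)
  expect_true(all(bf$pairwise$p_adj <= 1))
  expect_false(identical(bf$pairwise$p_adj, tk$pairwise$p_adj))
})
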
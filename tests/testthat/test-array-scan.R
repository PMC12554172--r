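test_that("peptide enumeration covers substitutions and truncations", {
  des <- array_design(rgs2_degron_sequence(), truncations = 16:5)
  peps <- enumerate_peptides(des)
  subs <- dplyr::filter(peps, type == "substitution")
  expect_equal(nrow(subs), 12 * 20)
  parent <- strsplit(rgs2_degron_sequence(), "")[[1]]
  non_parent <- dplyr::filter(subs, residue != parent[position - 4])
  expect_equal(nrow(non_parent), 12 * 19)
  expect_equal(dplyr::n_distinct(non_parent$sequence), 228)

  truncs <- dplyr::filter(peps, type == "truncation")
  expect_equal(nrow(truncs), 12)
  expect_equal(min(nchar(truncs$sequence)), 1)
  expect_equal(truncs$sequence[truncs$last_retained == 5], "M")

  # no truncations -> substitutions only
  des0 <- array_design(rgs2_degron_sequence())
  expect_true(all(enumerate_peptides(des0)$type == "substitution"))

  expect_error(
    array_design(rgs2_degron_sequence(), alphabet = c("A", "C")),
    class = "degronmap_error_residue"
  )
})

test_that("parent normalization satisfies its invariants", {
  prof <- effect_profile(
    rgs2_degron_sequence(),
    effects = tibble::tibble(position = 7, residue = "S", factor = 0.25)
  )
  arr <- gen_array_signals(prof, parent_signal = 2000)
  nm <- normalize_to_parent(arr)
  expect_equal(
    dplyr::filter(nm, position == 7, residue == "S")$mean_pct, 25
  )

  # noiseless round trip: mean_pct = 100 * effect everywhere
  prof2 <- rgs2_degron_profile()
  arr2 <- gen_array_signals(prof2, 1000)
  nm2 <- normalize_to_parent(arr2) |>
    dplyr::left_join(prof2$effect, by = c("position", "residue"))
  expect_equal(nm2$mean_pct, 100 * nm2$factor)

  # parent cells pinned at exactly 100 under noise
  arrn <- gen_array_signals(prof2, 1000, default_noise_config(3))
  nmn <- normalize_to_parent(arrn)
  parent <- strsplit(rgs2_degron_sequence(), "")[[1]]
  pcells <- dplyr::filter(nmn, residue == parent[position - 4])
  expect_equal(pcells$mean_pct, rep(100, 12))
  expect_equal(pcells$sd_pct, rep(0, 12))

  # scale invariance: rescaling one replicate globally changes nothing
  arr_scaled <- arrn
  arr_scaled$signal[arr_scaled$replicate == 2] <-
    arr_scaled$signal[arr_scaled$replicate == 2] * 7
  expect_equal(
    as.data.frame(normalize_to_parent(arr_scaled)),
    as.data.frame(nmn)
  )

  # pooled method: parent cell keeps its replicate scatter
  nmp <- normalize_to_parent(arrn, method = "pooled")
  pcells_p <- dplyr::filter(nmp, residue == parent[position - 4])
  expect_equal(pcells_p$mean_pct, rep(100, 12))
  expect_true(all(pcells_p$sd_pct > 0))
})

test_that("near-zero parent signal is rejected naming the position", {
  prof <- rgs2_degron_profile()
  arr <- gen_array_signals(prof, 1000)
  parent <- strsplit(rgs2_degron_sequence(), "")[[1]]
  bad <- arr$type == "substitution" & arr$position == 5 &
    arr$residue == parent[1]
  arr$signal[bad] <- 0
  expect_error(normalize_to_parent(arr),
    regexp = "5",
    class = "degronmap_error_parent_signal"
  )
})

test_that("Tukey simple effects match the emmeans oracle", {
  skip_if_not_installed("emmeans")
  prof <- effect_profile(
    "MFC",
    effects = tibble::tibble(
      position = c(7, 7, 6), residue = c("S", "R", "K"),
      factor = c(0.1, 1.8, 1.4)
    )
  )
  arr <- gen_array_signals(prof, 1000, default_noise_config(21,
    n_replicates = 3, noise_scale = 0.1
  ))
  tab <- test_substitution_effects(arr)

  design <- attr(arr, "design")
  parents <- dplyr::filter(
    arr, type == "substitution",
    residue == design$parent_at[as.character(position)]
  ) |>
    dplyr::select(position, replicate, parent_signal = signal)
  vals <- dplyr::filter(arr, type == "substitution") |>
    dplyr::left_join(parents, by = c("position", "replicate")) |>
    dplyr::mutate(
      value = 100 * signal / parent_signal,
      fpos = factor(position), fres = factor(residue)
    )
  fit <- aov(value ~ fpos * fres, data = vals)
  emm <- emmeans::emmeans(fit, ~ fres | fpos)
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))

  parent <- c(`5` = "M", `6` = "F", `7` = "C")
  for (pos in c(5, 6, 7)) {
    p_parent <- parent[[as.character(pos)]]
    sub <- prs[prs$fpos == pos, ]
    involves <- grepl(paste0("\\b", p_parent, "\\b"), sub$contrast)
    sub <- sub[involves, ]
    # map each contrast row to the non-parent residue
    other <- gsub(" - ", " ", sub$contrast)
    other <- vapply(strsplit(other, " "), function(x) setdiff(x, p_parent), "")
    mine <- tab[tab$position == pos & tab$residue %in% other, ]
    mine <- mine[match(other, mine$residue), ]
    expect_equal(mine$p_adj, sub$p.value, tolerance = 1e-6)
    expect_equal(abs(mine$estimate), abs(sub$estimate), tolerance = 1e-8)
  }
})

test_that("degenerate significance inputs behave as specified", {
  # zero-variance null: all cells identical, nothing flagged
  prof <- effect_profile(rgs2_degron_sequence())
  arr0 <- gen_array_signals(prof, 1000)
  tab0 <- test_substitution_effects(arr0)
  expect_false(any(tab0$significant, na.rm = TRUE))
  parent <- strsplit(rgs2_degron_sequence(), "")[[1]]
  pr <- dplyr::filter(tab0, residue == parent[position - 4])
  expect_true(all(is.na(pr$p_adj)))
  expect_false(any(pr$significant))
  expect_equal(pr$estimate, rep(0, 12))

  # single replicate: descriptive table with warning, no p-values
  arr1 <- gen_array_signals(
    rgs2_degron_profile(), 1000, generator_config(seed = 1, n_replicates = 1)
  )
  expect_warning(tab1 <- test_substitution_effects(arr1), "single replicate")
  expect_true(all(is.na(tab1$p_adj)))
})

test_that("position classification recovers the planted degron pattern", {
  prof <- rgs2_degron_profile()
  arr <- gen_array_signals(prof, 1000, default_noise_config(7))
  cls <- classify_positions(
    normalize_to_parent(arr), test_substitution_effects(arr)
  )
  expect_equal(cls$category[cls$position == 13], "essential")
  expect_true(all(cls$category[cls$position %in% 5:10] == "tolerant"))
  expect_equal(cls$category[cls$position == 12], "charge-enhanced")
  expect_gt(cls$n_flagged_increase[cls$position == 12], 0)

  # flat profile -> all tolerant
  flat <- gen_array_signals(
    effect_profile(rgs2_degron_sequence()), 1000, default_noise_config(8)
  )
  cls_flat <- classify_positions(
    normalize_to_parent(flat), test_substitution_effects(flat)
  )
  expect_true(all(cls_flat$category %in% c("tolerant", "mixed", "charge-enhanced")))
  expect_false(any(cls_flat$category == "essential"))
})

test_that("truncation boundary is the first below-threshold cut", {
  # hand case: factors 16 -> 1.0, 15 -> 0.6, 14 -> 0.4, threshold 50%
  prof <- effect_profile(
    rgs2_degron_sequence(),
    truncation_effects = c(`16` = 1.0, `15` = 0.6, `14` = 0.4)
  )
  arr <- gen_array_signals(prof, 1000)
  expect_equal(truncation_boundary(arr, loss_threshold = 50)$boundary, 15L)

  # no truncation crosses the threshold -> sentinel
  prof1 <- effect_profile(
    rgs2_degron_sequence(),
    truncation_effects = setNames(rep(1, 12), 16:5)
  )
  arr1 <- gen_array_signals(prof1, 1000)
  expect_true(is.na(truncation_boundary(arr1, 20)$boundary))

  # planted degron cliff below Cys13 with realistic noise
  arr2 <- gen_array_signals(rgs2_degron_profile(), 1000, default_noise_config(9))
  expect_equal(truncation_boundary(arr2)$boundary, 13L)
})
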
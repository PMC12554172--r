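test_that("noiseless array signals equal parent_signal times the effect factor", {
  prof <- effect_profile(
    rgs2_degron_sequence(),
    effects = tibble::tibble(position = 13, residue = "S", factor = 0.02),
    truncation_effects = c(`16` = 1, `12` = 0.5)
  )
  arr <- gen_array_signals(prof, parent_signal = 1000)

  s13 <- dplyr::filter(arr, position == 13, residue == "S")
  expect_equal(s13$signal, rep(20, 3))

  parent <- strsplit(rgs2_degron_sequence(), "")[[1]]
  parents <- dplyr::filter(
    arr, type == "substitution",
    residue == parent[position - 4]
  )
  expect_equal(parents$signal, rep(1000, nrow(parents)))

  t12 <- dplyr::filter(arr, type == "truncation", last_retained == 12)
  expect_equal(t12$signal, rep(500, 3))
})

test_that("generators are deterministic in the seed and diverge across seeds", {
  prof <- rgs2_degron_profile()
  make_all <- function(seed) {
    cfg <- generator_config(
      seed = seed, noise_model = "multiplicative-lognormal", noise_scale = 0.1
    )
    occ <- tibble::tibble(
      receptor_resno = 234, peptide_resno = 13, occupancy = 0.5
    )
    list(
      arr = gen_array_signals(prof, 1000, cfg),
      trj = gen_trajectories(
        n_poses = 1, n_trials = 2, n_frames = 20,
        occupancy = occ, config = cfg, drift = 0.2
      ),
      iso = gen_isotherm(2.1, 100, nonspecific_slope = 1, config = cfg),
      chs = gen_chase(19.5, config = cfg)
    )
  }
  a <- make_all(42)
  b <- make_all(42)
  c <- make_all(43)
  for (nm in names(a)) {
    expect_identical(a[[nm]], b[[nm]], info = nm)
    expect_false(isTRUE(all.equal(a[[nm]], c[[nm]])), info = nm)
  }
})

test_that("generator inputs are validated with named errors", {
  expect_error(generator_config(noise_scale = -0.1),
    class = "degronmap_error_argument"
  )
  expect_error(
    effect_profile("MFX"),
    class = "degronmap_error_residue"
  )
  expect_error(
    effect_profile("MF",
      effects = tibble::tibble(position = 5, residue = "B", factor = 1)
    ),
    class = "degronmap_error_residue"
  )
  expect_error(gen_isotherm(kd = -1, bmax = 100),
    class = "degronmap_error_argument"
  )
  expect_error(gen_isotherm(kd = 1, bmax = 0),
    class = "degronmap_error_argument"
  )
  expect_error(gen_chase(t_half = 0), class = "degronmap_error_argument")
  expect_error(gen_chase(19.5, timepoints = c(10, 20)),
    class = "degronmap_error_argument"
  )
  occ_bad <- tibble::tibble(
    receptor_resno = 234, peptide_resno = 13, occupancy = 1.2
  )
  expect_error(gen_trajectories(occupancy = occ_bad),
    class = "degronmap_error_occupancy"
  )
})

test_that("the transposed degron spelling is accepted with a warning", {
  expect_warning(effect_profile("MFLAVQHDRCPM"), "transposed")
  expect_warning(array_design("MFLAVQHDRCPM"), "transposed")
  expect_silent(p <- effect_profile("MFLAVQHDCRPM"))
  expect_equal(p$parent_sequence, rgs2_degron_sequence())
})

test_that("noiseless isotherms follow the Langmuir model exactly", {
  conc <- c(0.5, 1, 2, 4, 8, 10)
  iso <- gen_isotherm(
    kd = 2, bmax = 100, conc_series = conc, nonspecific_slope = 2
  )
  specific <- iso$ru_measurement - iso$ru_reference
  # half-saturation identity at C = Kd
  expect_equal(specific[conc == 2], 50)
  # reference channel is pure nonspecific binding
  expect_equal(iso$ru_reference[conc == 10], 20)
  # saturation limit
  iso_hi <- gen_isotherm(kd = 2, bmax = 100, conc_series = c(1, 10, 100, 2000))
  expect_lt(abs(100 - max(iso_hi$ru_measurement)) / 100, 0.001)
})

test_that("noiseless chase courses follow the half-life law exactly", {
  ch <- gen_chase(19.5, timepoints = c(0, 19.5, 60))
  expect_equal(
    dplyr::filter(ch, timepoint_min == 0)$abundance_pct, rep(100, 3)
  )
  expect_equal(
    dplyr::filter(ch, timepoint_min == 19.5)$abundance_pct, rep(50, 3)
  )
  expect_equal(
    dplyr::filter(ch, timepoint_min == 60)$abundance_pct,
    rep(100 * 2^(-60 / 19.5), 3)
  )
})

test_that("trajectory occupancies are realized at the prescribed rate", {
  occ <- tibble::tibble(
    receptor_resno = c(234, 226, 235),
    peptide_resno = c(13, 5, 14),
    occupancy = c(1, 0, 0.75)
  )
  ens <- gen_trajectories(
    n_poses = 1, n_trials = 4, n_frames = 200, occupancy = occ
  )
  cm <- contact_frequency(ens, 1, contact_params(burn_in = 0))
  freq <- function(r, p) {
    cm$frequency[cm$receptor_resno == r & cm$peptide_resno == p]
  }
  expect_identical(freq(234, 13), 1)
  expect_identical(freq(226, 5), 0)
  expect_lte(abs(freq(235, 14) - 0.75), 1 / 200)
  # unlisted cross-chain pairs stay beyond 1.2 nm
  others <- dplyr::anti_join(
    cm, occ,
    by = c("receptor_resno", "peptide_resno")
  )
  expect_true(all(others$frequency == 0))
  wide <- dplyr::filter(ens, trial == 1, frame == 1)
  rec <- dplyr::filter(wide, chain == "receptor")
  pep <- dplyr::filter(wide, chain == "peptide")
  dmat <- outer(seq_len(nrow(rec)), seq_len(nrow(pep)), Vectorize(function(i, j) {
    sqrt((rec$x[i] - pep$x[j])^2 + (rec$y[i] - pep$y[j])^2 +
      (rec$z[i] - pep$z[j])^2)
  }))
  listed <- cbind(
    match(occ$receptor_resno, rec$resno),
    match(occ$peptide_resno, pep$resno)
  )
  dmat[listed] <- NA
  expect_true(all(dmat >= 1.2, na.rm = TRUE))
})

test_that("user-supplied baseline geometry is honored", {
  geom <- tibble::tibble(
    chain = rep(c("receptor", "peptide"), c(4, 3)),
    resno = c(1:4, 11:13),
    x = c(0, 5, 10, 15, 0.3, 0.6, 0.9),
    y = c(0, 0.4, 0, 0.4, 4, 4.2, 4.1),
    z = c(0, 0, 0.3, 0.3, 0.2, 0, 0.1)
  )
  ens <- gen_trajectories(
    n_poses = 1, n_trials = 1, n_frames = 2, geometry = geom
  )
  f1 <- dplyr::arrange(
    dplyr::filter(ens, frame == 1), dplyr::desc(chain), resno
  )
  expect_equal(f1$x, geom$x)
  expect_equal(f1$y, geom$y)
  # occupancy naming residues absent from the geometry is rejected
  occ <- tibble::tibble(
    receptor_resno = 99, peptide_resno = 11, occupancy = 1
  )
  expect_error(
    gen_trajectories(n_frames = 2, occupancy = occ, geometry = geom),
    class = "degronmap_error_occupancy"
  )
})

test_that("array datasets round-trip through TSV", {
  arr <- gen_array_signals(
    rgs2_degron_profile(), 1000,
    default_noise_config(2, n_replicates = 2, noise_scale = 0.1)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_array_tsv(arr, f)
  back <- read_array_tsv(f, attr(arr, "design"))
  expect_equal(as.data.frame(back), as.data.frame(arr))
  expect_s3_class(normalize_to_parent(back), "normalized_matrix")
})

test_that("generator outputs pass the consuming modules' validation", {
  cfg <- default_noise_config(seed = 11, n_replicates = 3, noise_scale = 0.1)
  arr <- gen_array_signals(rgs2_degron_profile(), 1000, cfg)
  expect_s3_class(normalize_to_parent(arr), "normalized_matrix")
  ens <- gen_trajectories(
    n_poses = 1, n_trials = 2, n_frames = 10, config = cfg
  )
  expect_s3_class(
    contact_frequency(ens, 1, contact_params(burn_in = 0)), "contact_map"
  )
  iso <- gen_isotherm(2.1, 100, nonspecific_slope = 1, config = cfg)
  expect_s3_class(fit_saturation(reference_subtract(iso)), "saturation_fit")
  expect_s3_class(fit_decay(gen_chase(19.5, config = cfg)), "decay_fit")
})
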
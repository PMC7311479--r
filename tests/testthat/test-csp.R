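make_sparky <- function(path, labels, n_ppm, h_ppm) {
  writeLines(c(" Assignment     w1     w2",
               sprintf("%12s %8.3f %8.3f", labels, n_ppm, h_ppm)), path)
  path
}

test_that("Sparky-style and CSV peak lists parse to identical data", {
  sp <- tempfile(fileext = ".list")
  make_sparky(sp, c("G109N-H", "A110N-H", "K111N-H"),
              c(110.5, 122.3, 118.9), c(8.21, 7.95, 9.03))
  pl <- read_peaklist(sp)
  expect_s3_class(pl, "peaklist")
  expect_equal(pl$residue, c(109L, 110L, 111L))
  expect_equal(pl$h_ppm, c(8.21, 7.95, 9.03))
  expect_equal(pl$n_ppm, c(110.5, 122.3, 118.9))

  cs <- tempfile(fileext = ".csv")
  write.csv(data.frame(residue = 109:111, h_ppm = c(8.21, 7.95, 9.03),
                       n_ppm = c(110.5, 122.3, 118.9)), cs, row.names = FALSE)
  pl2 <- read_peaklist(cs)
  expect_equal(pl2$residue, pl$residue)
  expect_equal(pl2$h_ppm, pl$h_ppm)
  expect_equal(pl2$n_ppm, pl$n_ppm)
})

test_that("duplicate residues are rejected by name", {
  expect_error(peaklist(c(41, 42, 42), c(8, 8.5, 9), c(110, 115, 120)),
               "42")
})

test_that("assignments without residue numbers are kept as unassigned", {
  sp <- tempfile(fileext = ".list")
  make_sparky(sp, c("G109N-H", "??-H"), c(110.5, 122.3), c(8.21, 7.95))
  expect_warning(pl <- read_peaklist(sp), "unassigned")
  expect_equal(sum(is.na(pl$residue)), 1L)
})

test_that("identical lists match completely at zero distance", {
  pair <- gen_peaklist_pair(csp_truth(spans = list(), jitter_h = 0,
                                      jitter_n = 0), seed = 1)
  m <- match_peaks(pair$reference, pair$modified)
  expect_equal(nrow(m$pairs), nrow(pair$reference))
  expect_true(all(m$pairs$dist == 0))
  expect_equal(nrow(m$unmatched_reference), 0L)
})

test_that("a uniform proton offset matches at the offset distance", {
  # well-separated peaks (0.2 ppm proton spacing >> 0.05 offset) so the
  # geometric assignment is unambiguous
  ref <- peaklist(1:20, seq(6.5, 10.3, by = 0.2), rep(115, 20))
  mod <- ref
  mod$h_ppm <- mod$h_ppm + 0.05
  m <- match_peaks(ref, mod, by_assignment = FALSE, cutoff = 0.2)
  expect_equal(nrow(m$pairs), 20L)
  expect_equal(m$pairs$dist, rep(0.05, 20), tolerance = 1e-10)
})

test_that("greedy distance matching agrees with the exhaustive assignment", {
  set.seed(99)
  agree <- 0L; compared <- 0L
  for (rep in 1:10) {
    n <- 6
    ref <- peaklist(1:n, runif(n, 6.5, 10.5), runif(n, 105, 130))
    mod <- ref
    mod$h_ppm <- mod$h_ppm + rnorm(n, 0, 0.01)
    mod$n_ppm <- mod$n_ppm + rnorm(n, 0, 0.1)
    m <- match_peaks(ref, mod, by_assignment = FALSE, cutoff = 0.2)
    opt <- assignment_oracle(ref, mod)
    greedy_total <- sum(m$pairs$dist)
    compared <- compared + 1L
    if (abs(greedy_total - opt$total) < 1e-9) {
      agree <- agree + 1L
      expect_equal(m$pairs$residue, seq_len(n))
    }
  }
  expect_equal(compared, 10L)
  expect_gte(agree, 8L)  # greedy is optimal on well-separated instances
})

test_that("csp formula: proton-only, nitrogen weighting, mixed case", {
  pairs <- data.frame(residue = 1:3,
                      h_ref = c(8, 8, 8), n_ref = c(110, 110, 110),
                      h_mod = c(8.1, 8, 8.03), n_mod = c(110, 111, 110.5))
  prof <- compute_csp(pairs)
  expect_equal(prof$csp[1], 0.1)
  expect_equal(prof$csp[2], 0.14)
  expect_equal(prof$csp[3], sqrt(0.03^2 + (0.14 * 0.5)^2))  # 0.07616
  expect_equal(round(prof$csp[3], 4), 0.0762)
})

test_that("csp is symmetric and offset-invariant; weight 1 is Euclidean", {
  pair <- gen_peaklist_pair(seed = 4)
  fwd <- compute_csp(match_peaks(pair$reference, pair$modified))
  rev <- compute_csp(match_peaks(pair$modified, pair$reference))
  expect_equal(fwd$csp, rev$csp)

  ref2 <- pair$reference; mod2 <- pair$modified
  ref2$h_ppm <- ref2$h_ppm + 0.3; ref2$n_ppm <- ref2$n_ppm + 2
  mod2$h_ppm <- mod2$h_ppm + 0.3; mod2$n_ppm <- mod2$n_ppm + 2
  shifted <- compute_csp(match_peaks(ref2, mod2))
  expect_equal(shifted$csp, fwd$csp)

  w1 <- compute_csp(match_peaks(pair$reference, pair$modified),
                    nitrogen_weight = 1)
  expect_equal(w1$csp, sqrt(fwd$delta_h^2 + fwd$delta_n^2))
})

test_that("trimmed mean + SD threshold matches spreadsheet arithmetic", {
  # all equal: SD = 0 so the threshold equals the common value
  expect_equal(csp_threshold(data.frame(csp = rep(0.04, 6))), 0.04)
  # {0,0,0,0,1}: first cut is mean + 3 SD = 1.54, nothing excluded,
  # so the threshold is mean + SD of the full set
  x <- c(0, 0, 0, 0, 1)
  expect_equal(csp_threshold(data.frame(csp = x)), mean(x) + sd(x))
  # a gross outlier is excluded before the threshold is formed
  y <- c(rep(0.01, 19), 10)
  expect_equal(csp_threshold(data.frame(csp = y)), 0.01)
  expect_equal(csp_threshold(data.frame(csp = y), method = "fixed",
                             value = 0.05), 0.05)
  expect_error(csp_threshold(data.frame(csp = c(1, 2))), "at least 5")
})

test_that("cluster detection finds contiguous runs and honours the gap rule", {
  prof <- data.frame(residue = 1:30, csp = 0.01)
  prof$csp[10:14] <- 0.2
  cl <- detect_clusters(prof, threshold = 0.1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_residue, 10L)
  expect_equal(cl$end_residue, 14L)

  # one internal gap allowed, two breaks the run
  prof2 <- data.frame(residue = 1:30, csp = 0.01)
  prof2$csp[c(10, 11, 13, 14)] <- 0.2
  expect_equal(nrow(detect_clusters(prof2, threshold = 0.1)), 1L)
  prof3 <- data.frame(residue = 1:30, csp = 0.01)
  prof3$csp[c(10, 11, 14, 15, 16)] <- 0.2
  cl3 <- detect_clusters(prof3, threshold = 0.1, max_gap = 1)
  expect_equal(cl3$start_residue, 14L)  # the 10-11 span (2 < 3) is dropped
})

test_that("cluster detection equals exhaustive run enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    csp <- abs(rnorm(30, 0.02, 0.03))
    prof <- data.frame(residue = 1:30, csp = csp)
    got <- detect_clusters(prof, threshold = 0.05)
    want <- cluster_enumeration_oracle(1:30, csp, 0.05)
    expect_equal(got$start_residue, want$start_residue)
    expect_equal(got$end_residue, want$end_residue)
  }
})

test_that("cluster output is invariant to profile row order", {
  pair <- gen_peaklist_pair(seed = 6)
  prof <- compute_csp(match_peaks(pair$reference, pair$modified))
  th <- csp_threshold(prof)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(detect_clusters(prof, th), detect_clusters(shuffled, th))
})

test_that("the S-nitrosylation perturbation pattern yields two clusters", {
  pair <- gen_peaklist_pair(csp_truth(), seed = 8)
  prof <- compute_csp(match_peaks(pair$reference, pair$modified))
  cl <- detect_clusters(prof, csp_threshold(prof))
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start_residue, c(68L, 112L))
  expect_equal(cl$end_residue, c(80L, 130L))
})

test_that("declared span perturbations give the exact csp at zero jitter", {
  tr <- csp_truth(spans = list(list(from = 70, to = 75, dh = 0.05,
                                    dn = 0.8)),
                  jitter_h = 0, jitter_n = 0)
  pair <- gen_peaklist_pair(tr, seed = 10)
  prof <- compute_csp(match_peaks(pair$reference, pair$modified))
  in_span <- prof$residue >= 70 & prof$residue <= 75
  expect_equal(prof$csp[in_span],
               rep(sqrt(0.05^2 + (0.14 * 0.8)^2), sum(in_span)))
  expect_equal(prof$csp[!in_span], rep(0, sum(!in_span)))
})

test_that("structure mapping writes 100*csp into the B-factor column", {
  pdb_in <- write_toy_pdb(tempfile(fileext = ".pdb"), resnos = 1:3)
  out <- tempfile(fileext = ".pdb")
  prof <- data.frame(residue = c(1L, 7L), csp = c(0.1, 0.5))
  res <- map_to_structure(prof, pdb_in, chain = "A", out_pdb = out,
                          threshold = 0.05)
  parsed <- bio3d::read.pdb(out)
  expect_equal(unique(parsed$atom$b[parsed$atom$resno == 1]), 10.00)
  expect_equal(unique(parsed$atom$b[parsed$atom$resno %in% 2:3]), 0)
  expect_equal(res$not_mapped, 7L)
  expect_true(all(res$table$above_threshold))
})

test_that("structure-mapping round trip recovers csp at format precision", {
  pair <- gen_peaklist_pair(csp_truth(residues = 1:20,
                                      spans = list(list(from = 5, to = 9,
                                                        dh = 0.08,
                                                        dn = 0.5))),
                            seed = 12)
  prof <- compute_csp(match_peaks(pair$reference, pair$modified))
  pdb_in <- write_toy_pdb(tempfile(fileext = ".pdb"), resnos = 1:20)
  out <- tempfile(fileext = ".pdb")
  map_to_structure(prof, pdb_in, chain = "A", out_pdb = out,
                   threshold = 0.05)
  parsed <- bio3d::read.pdb(out)
  for (i in seq_len(nrow(prof))) {
    b <- unique(parsed$atom$b[parsed$atom$resno == prof$residue[i]])
    # B-factor column carries two decimals: absolute error at most 0.005
    expect_lte(abs(b - 100 * prof$csp[i]), 0.005 + 1e-9)
  }
})

test_that("zero residue overlap is an error naming both ranges", {
  pdb_in <- write_toy_pdb(tempfile(fileext = ".pdb"), resnos = 1:3)
  prof <- data.frame(residue = 100:105, csp = 0.1)
  expect_error(map_to_structure(prof, pdb_in, threshold = 0.05),
               "100-105.*1-3")
})
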
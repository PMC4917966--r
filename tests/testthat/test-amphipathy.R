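test_that("hydrophobic moments match the direct complex-sum oracle", {
  # independent direct sum
  direct_mu <- function(res, scale, twist = 100) {
    h <- unname(scale[res])
    ang <- (seq_along(res) - 1) * twist * pi / 180
    sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(res)
  }
  scale <- hydrophobicity_scale("fauchere_pliska")
  win <- strsplit("IKEFREFAMRG", "")[[1L]]   # EcMscL residues 4-14
  m <- hydrophobic_moment(win)
  expect_equal(m$mu_h, direct_mu(win, scale), tolerance = 1e-12)
  expect_gt(m$mu_h, 0.45)

  set.seed(3)
  for (k in 1:10) {
    res <- sample(names(scale), 11, replace = TRUE)
    expect_equal(hydrophobic_moment(res)$mu_h, direct_mu(res, scale),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and idealized windows behave analytically", {
  # constant hydrophobicity cancels over complete turns: poly-A, 18 residues
  # spans exactly 5 turns at 100 degrees/residue
  expect_equal(hydrophobic_moment(strrep("A", 18))$mu_h, 0, tolerance = 1e-9)
  # perfect period-2 amphipathic pattern at 180 degrees twist: mu_H = mean|H|
  scale <- c(A = 1, G = -1)[c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                              "I", "L", "K", "M", "F", "P", "S", "T", "W",
                              "Y", "V")]
  scale <- stats::setNames(rep(c(1, -1), 10), names(hydrophobicity_scale()))
  seqv <- rep(c("I", "E"), 6)
  sc <- stats::setNames(rep(0, 20), names(hydrophobicity_scale()))
  sc["I"] <- 2; sc["E"] <- -2
  m <- hydrophobic_moment(seqv, scale = sc, twist = 180)
  expect_equal(m$mu_h, 2, tolerance = 1e-9)
  expect_error(hydrophobic_moment("AG"), "at least 3")
  expect_error(peptide_sequence("ABZ"), "invalid residue")
})

test_that("charge statistics follow the helical-wheel convention", {
  cs <- charge_stats("GGGG")
  expect_equal(cs$net_charge, 0L)
  expect_equal(cs$charged_fraction, 0)

  cs2 <- charge_stats("MSIIKEFREFAMRG")   # EcMscL 1-14
  expect_equal(cs2$net_charge, 1L)        # K5, R8, R13 vs E6, E9
  expect_equal(cs2$charged_fraction, 100 * 5 / 14, tolerance = 1e-9)

  cs3 <- charge_stats("KRKR")
  expect_equal(cs3$net_charge, 4L)
  expect_equal(cs3$charged_fraction, 100)
  # histidine is neutral by convention
  expect_equal(charge_stats("HHHH")$net_charge, 0L)
})

test_that("wheel coordinates wrap at complete turns and track the moment", {
  wc <- wheel_coordinates("MSIIKEFREFAMRGNVVDL")
  expect_equal(wc$azimuth[1L], 0)
  expect_equal(wc$radius, rep(1, nrow(wc)))
  expect_equal(wc$azimuth[19L], wc$azimuth[1L])   # residue 18 = 1800 deg

  # hydrophobic-face azimuth: the moment direction points toward the
  # hydrophobicity-weighted side of the wheel
  win <- strsplit("IKEFREFAMRG", "")[[1L]]
  m <- hydrophobic_moment(win)
  wcw <- wheel_coordinates(win)
  vx <- sum(wcw$hydrophobicity * cos(wcw$azimuth * pi / 180))
  vy <- sum(wcw$hydrophobicity * sin(wcw$azimuth * pi / 180))
  expect_equal((atan2(vy, vx) * 180 / pi) %% 360, m$azimuth,
               tolerance = 1e-9)
})

test_that("motif scanning finds the consensus at the right position", {
  motif <- mscl_consensus_motif()
  expect_equal(motif$width, 8L)
  # round-trips through its text form
  expect_equal(format(sequence_motif(format(motif))), format(motif))

  hits <- motif_scan("MSIIKEFREFAMRGN", motif)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 7L)
  expect_equal(hits$match, "FREFAMRG")

  expect_equal(nrow(motif_scan("", motif)), 0L)
  expect_error(sequence_motif("F-[K,R]-x(2)-G"), "malformed")
  expect_error(sequence_motif("F-[K,B]-G"), "invalid residue")

  # every bundled homologue carries the consensus
  for (nm in names(mscl_nterm_sequences())) {
    h <- motif_scan(mscl_nterm_sequences()[[nm]], motif)
    expect_gte(nrow(h), 1L)
  }
})

test_that("overlapping matches are all reported", {
  m <- sequence_motif("A-x-A")
  hits <- motif_scan("AAAAA", m)
  expect_equal(hits$start, 1:3)
})

test_that("numbering offsets shift reported positions", {
  s <- peptide_sequence("FREFAMRG", offset = 6L)
  hits <- motif_scan(s, mscl_consensus_motif())
  expect_equal(hits$start, 7L)
  m <- max_hydrophobic_moment(s)
  expect_equal(m$start, 7L)
})

test_that("motif scan agrees with a brute-force matcher on random input", {
  motif <- mscl_consensus_motif()
  brute <- function(res, classes) {
    w <- length(classes)
    out <- integer(0)
    if (length(res) >= w)
      for (i in 1:(length(res) - w + 1))
        if (all(vapply(1:w, function(j) res[i + j - 1] %in% classes[[j]],
                       TRUE)))
          out <- c(out, i)
    out
  }
  set.seed(19)
  aa <- names(hydrophobicity_scale())
  for (k in 1:500) {
    res <- sample(aa, 20, replace = TRUE)
    got <- motif_scan(res, motif)$start
    expect_identical(as.integer(got), brute(res, motif$classes))
  }
})
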
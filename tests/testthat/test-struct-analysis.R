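test_that("CA PDB writer and reader round-trip structures and trajectories", {
    set.seed(10)
    s <- CaStructure(1:5, matrix(round(rnorm(15, sd = 5), 3), 5))
    tmp <- withr::local_tempfile(fileext = ".pdb")
    writeCaPdb(s, tmp)
    r <- readCaPdb(tmp)
    expect_s4_class(r, "CaStructure")
    expect_equal(residueIds(r), 1:5)
    expect_equal(unname(caCoords(r)), unname(caCoords(s)), tolerance = 1e-9)

    traj <- simulateTrajectory(nResidues = 8, nFrames = 3,
                               rmsfAmplitudes = 0.4, rngSeed = 2)
    tmp2 <- withr::local_tempfile(fileext = ".pdb")
    writeCaPdb(traj, tmp2)
    r2 <- readCaPdb(tmp2)
    expect_s4_class(r2, "CaTrajectory")
    expect_equal(nFrames(r2), 3L)
    # PDB precision: 3 decimals
    expect_equal(caCoords(trajFrame(r2, 2)), caCoords(trajFrame(traj, 2)),
                 tolerance = 1e-3)
    expect_error(readCaPdb(withr::local_tempfile()), "not found")
})

test_that("superposing a structure onto itself is the identity", {
    s <- trajFrame(simulateTrajectory(nResidues = 10, nFrames = 1,
                                      rngSeed = 1), 1)
    fit <- kabschSuperpose(s, s, residueIds(s))
    expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
    expect_equal(fit$translation, rep(0, 3), tolerance = 1e-12)
    expect_equal(fit$fitRmsd, 0, tolerance = 1e-12)
})

test_that("a planted rigid transform is recovered to numerical precision", {
    base <- trajFrame(simulateTrajectory(nResidues = 12, nFrames = 1,
                                         rngSeed = 3), 1)
    # 90 degrees about z plus a shift
    R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
    moved <- CaStructure(residueIds(base),
                         rigidTransform(caCoords(base), R90, c(3, -2, 7)))
    fit <- kabschSuperpose(moved, base, residueIds(base))
    expect_lt(fit$fitRmsd, 1e-10)
    expect_equal(fit$rotation %*% R90, diag(3), tolerance = 1e-9)
    expect_equal(unname(caCoords(fit$transformed)),
                 unname(caCoords(base)), tolerance = 1e-9)
    # random transforms too
    for (seed in 1:5) {
        tr <- randomTransform(seed)
        moved <- CaStructure(residueIds(base),
                             rigidTransform(caCoords(base), tr$rotation,
                                            tr$translation))
        expect_lt(kabschSuperpose(moved, base,
                                  residueIds(base))$fitRmsd, 1e-9)
    }
})

test_that("the Kabsch fit beats random rigid transforms and bio3d agrees", {
    set.seed(17)
    a <- CaStructure(1:10, matrix(rnorm(30, sd = 4), 10))
    b <- CaStructure(1:10, matrix(rnorm(30, sd = 4), 10))
    fit <- kabschSuperpose(a, b, 1:10)
    rmsdOf <- function(co) sqrt(mean(rowSums((co - caCoords(b))^2)))
    for (i in 1:200) {
        tr <- randomTransform(i)
        expect_gte(rmsdOf(rigidTransform(caCoords(a), tr$rotation,
                                         tr$translation)),
                   fit$fitRmsd - 1e-9)
    }
    # independent implementation check
    xyz <- bio3d::fit.xyz(as.vector(t(caCoords(b))),
                          as.vector(t(caCoords(a))),
                          fixed.inds = 1:30, mobile.inds = 1:30)
    expect_equal(fit$fitRmsd,
                 sqrt(mean(rowSums((matrix(xyz, 10, byrow = TRUE) -
                                    caCoords(b))^2))),
                 tolerance = 1e-6)
})

test_that("superposition is proper and invariant to rigid pre-transforms", {
    set.seed(23)
    a <- CaStructure(1:8, matrix(rnorm(24, sd = 3), 8))
    b <- CaStructure(1:8, matrix(rnorm(24, sd = 3), 8))
    base <- kabschSuperpose(a, b, 1:8)
    for (seed in 1:10) {
        tr <- randomTransform(seed)
        pre <- CaStructure(1:8, rigidTransform(caCoords(a), tr$rotation,
                                               tr$translation))
        fit <- kabschSuperpose(pre, b, 1:8)
        expect_equal(fit$fitRmsd, base$fitRmsd, tolerance = 1e-9)
        expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    }
    # near-planar points must still give a proper rotation, not a reflection
    flat <- matrix(c(rnorm(16), rnorm(8, sd = 1e-9)), 8)
    mirrored <- flat %*% diag(c(1, 1, -1))
    fit <- kabschSuperpose(CaStructure(1:8, mirrored),
                           CaStructure(1:8, flat), 1:8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_error(kabschSuperpose(a, b, 1:2), "at least 3")
})

test_that("regional RMSD has its closed forms and symmetry", {
    s <- trajFrame(simulateTrajectory(nResidues = 10, nFrames = 1,
                                      rngSeed = 4), 1)
    expect_equal(regionRmsd(s, s, 1:10), 0)
    shifted <- CaStructure(1:10, sweep(caCoords(s), 2,
                                       c(-3, -4, 0)))
    expect_equal(regionRmsd(s, shifted, 1:10), 5)       # 3-4-5 triangle
    expect_equal(regionRmsd(s, shifted, c(2, 7)), 5)
    set.seed(6)
    t2 <- CaStructure(1:10, caCoords(s) + matrix(rnorm(30), 10))
    expect_equal(regionRmsd(s, t2, 3:8), regionRmsd(t2, s, 3:8))
    # independent arithmetic
    d <- caCoords(s)[3:8, ] - caCoords(t2)[3:8, ]
    acc <- 0
    for (i in 1:6) acc <- acc + sum(d[i, ]^2)
    expect_equal(regionRmsd(s, t2, 3:8), sqrt(acc / 6), tolerance = 1e-12)
    expect_error(regionRmsd(s, t2, integer(0)), "empty")
    expect_error(regionRmsd(s, t2, 99), "absent")
})

test_that("RMSF recovers static and single-oscillator closed forms", {
    static <- simulateTrajectory(nResidues = 6, nFrames = 5,
                                 rmsfAmplitudes = 0, rngSeed = 1)
    expect_equal(unname(rmsf(static)), rep(0, 6))
    # residue 3 oscillates +/- d along x, others static
    d <- 0.8
    base <- caCoords(trajFrame(static, 1))
    frames <- lapply(1:4, function(f) {
        co <- base
        co[3, 1] <- co[3, 1] + d * c(1, -1, 1, -1)[f]
        co
    })
    traj <- CaTrajectory(1:6, frames)
    fl <- rmsf(traj)
    expect_equal(unname(fl[3]), d)
    expect_equal(unname(fl[-3]), rep(0, 5))
    # brute-force two-pass oracle on a random trajectory
    rt <- simulateTrajectory(nResidues = 5, nFrames = 20,
                             rmsfAmplitudes = 0.7, rngSeed = 9)
    fl2 <- rmsf(rt)
    for (i in 1:5) {
        xyz <- t(rt@coords[i, , ])
        mu <- colMeans(xyz)
        expect_equal(unname(fl2[i]),
                     sqrt(mean(rowSums(sweep(xyz, 2, mu)^2))),
                     tolerance = 1e-12)
    }
    expect_error(rmsf(simulateTrajectory(nFrames = 1)), "at least 2")
})

test_that("curve smoothing reproduces linear data and damps noise", {
    t <- 1:20
    lin <- 0.3 * t + 2
    expect_equal(smoothCurve(t, lin)$smoothed, lin, tolerance = 1e-6)
    const <- rep(4, 20)
    expect_equal(smoothCurve(t, const)$smoothed, const, tolerance = 1e-6)
    set.seed(12)
    tt <- seq(0, 4 * pi, length.out = 100)
    noise <- rnorm(100, sd = 0.3)
    noisy <- sin(tt) + noise
    sm <- smoothCurve(tt, noisy)$smoothed
    expect_lt(var(noisy - sm), var(noise))
    expect_error(smoothCurve(1:3, 1:3), "at least 4")
})
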
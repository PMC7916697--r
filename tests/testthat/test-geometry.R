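# Point-charge Coulomb model of the domain-III lysine interference.

test_that("Coulomb force reproduces the reference Ca-Asp and Ca-Lys forces", {
    ch <- defaultCharges()
    attr_ <- coulombForce(ch$ca, ch$asp, 4.3)
    expect_equal(attr_$force, 2.489e-9, tolerance = 1e-3)
    expect_identical(attr_$interaction, "attraction")
    rep_ <- coulombForce(ch$ca, ch$lys, 8.1)
    expect_equal(rep_$force, 0.702e-9, tolerance = 1e-3)
    expect_identical(rep_$interaction, "repulsion")
})

test_that("Coulomb force obeys zero-charge and inverse-square behaviour", {
    q0 <- pointCharge("neutral", 0)
    expect_equal(coulombForce(pointCharge("Ca2+", 2), q0, 3.7)$force, 0)
    expect_identical(coulombForce(pointCharge("Ca2+", 2), q0, 3.7)$interaction,
                     "none")
    ch <- defaultCharges()
    for (d in c(1.7, 4.3, 9.2))
        expect_equal(coulombForce(ch$ca, ch$asp, 2 * d)$force,
                     coulombForce(ch$ca, ch$asp, d)$force / 4)
    expect_error(coulombForce(ch$ca, ch$asp, 0), "positive")
    expect_error(coulombForce(ch$ca, ch$asp, -1), "positive")
})

test_that("elementary-charge choice shifts the forces as documented", {
    ch <- defaultCharges()
    codata <- coulombConstants(e = 1.602176634e-19)
    expect_equal(coulombForce(ch$ca, ch$asp, 4.3, codata)$force,
                 2.495e-9, tolerance = 1e-3)
})

test_that("collinear far-side lysine sits at r = a + b exactly", {
    expect_equal(lysineDistance(interferenceGeometry(4.3, 3.8, theta = 0,
                                                     phi = 0)), 8.1)
    expect_equal(lysineDistance(interferenceGeometry(2, 5, theta = 0,
                                                     phi = 0)), 7)
})

test_that("degenerate and infeasible geometries raise", {
    # equal distances with the near-side branch put the lysine on top of Ca
    expect_error(lysineDistance(interferenceGeometry(4.3, 4.3, theta = 0,
                                                     phi = 180)),
                 "infeasible")
    # no triangle exists when b < a sin(theta)
    expect_error(interferenceGeometry(5, 1, theta = 60), "infeasible")
    expect_error(validObject(new("InterferenceGeometry", a = 5, b = 1,
                                 theta = 60, phi = 0)), "infeasible")
    expect_error(interferenceGeometry(4, 3, theta = 95), "theta")
    expect_error(interferenceGeometry(-1, 3), "positive")
})

test_that("triangle solver agrees with the coordinate oracle", {
    set.seed(42)
    scenes <- feasibleScenes(1000)
    for (sc in scenes) {
        r <- lysineDistance(interferenceGeometry(sc$a, sc$b, sc$theta, sc$phi))
        expect_equal(r, sc$r, tolerance = 1e-9 / max(1, sc$r))
    }
    # phi consistency validation accepts the measured angle and rejects a
    # contradictory one
    sc <- scenes[[1]]
    g <- interferenceGeometry(sc$a, sc$b, sc$theta, sc$phi)
    expect_equal(lysineDistance(g, validatePhi = TRUE), sc$r,
                 tolerance = 1e-9)
    wrongPhi <- if (sc$phi < 90) min(180, sc$phi + 60) else max(0, sc$phi - 60)
    gBad <- interferenceGeometry(sc$a, sc$b, sc$theta, wrongPhi)
    expect_error(lysineDistance(gBad, validatePhi = TRUE), "inconsistent")
})

test_that("axial repulsion matches the projected Coulomb vector", {
    ch <- defaultCharges()
    expect_equal(repellentComponent(ch$ca, ch$lys, r = 8.1, theta = 0),
                 0.702e-9, tolerance = 1e-3)
    # cos(90 deg) limit: the component vanishes
    expect_equal(repellentComponent(ch$ca, ch$lys, r = 5, theta = 89.9999),
                 0, tolerance = 1e-14)
    set.seed(43)
    for (sc in feasibleScenes(200)) {
        expect_lt(abs(repellentComponent(ch$ca, ch$lys, sc$r, sc$theta) -
                      projectedRepulsion(sc)), 1e-18)
    }
    expect_error(repellentComponent(ch$ca, ch$lys, r = -1, theta = 0),
                 "positive")
    expect_error(repellentComponent(ch$ca, ch$lys, r = 5, theta = 90),
                 "theta")
})

test_that("net attraction equals attraction minus axial repulsion", {
    g <- interferenceGeometry(4.3, 3.8, theta = 0, phi = 0)
    expect_equal(netAttraction(g), 2.489e-9 - 0.702e-9, tolerance = 1e-3)
    # removing the lysine charge leaves the pure attraction
    ch <- defaultCharges()
    ch$lys <- pointCharge("Lys0", 0)
    expect_equal(netAttraction(g, charges = ch),
                 coulombForce(ch$ca, ch$asp, 4.3)$force)
})

test_that("net force increases with lysine distance and crosses zero at a*sqrt(qK/|qD|)", {
    prof <- forceProfile(4.3, r = seq(8.1, 2.1, by = -0.5))
    expect_true(all(diff(prof$f_net_N) < 0))
    expect_true(any(prof$f_net_N < 0) && any(prof$f_net_N > 0))
    # closed-form root r* = a for |qD| = qK = 1, theta = 0, checked by
    # bisection on the profile function
    root <- uniroot(function(r) forceProfile(4.3, r)$f_net_N,
                    c(2.5, 7), tol = 1e-10)$root
    expect_equal(root, 4.3, tolerance = 1e-6)
})

test_that("minimal-interference configuration reproduces the headline reduction", {
    mi <- minimalInterference(4.3, 3.8)
    expect_equal(mi$fAttract, 2.489e-9, tolerance = 1e-3)
    expect_equal(mi$fRepel, 0.702e-9, tolerance = 1e-3)
    expect_equal(mi$r, 8.1)
    expect_gte(mi$reductionPercent, 28)
    expect_equal(mi$reductionPercent, 28.18, tolerance = 1e-3)
    # hand evaluation of the ke-cancelling ratio qK*a^2/(|qD|*(a+b)^2):
    # a = b gives 100 * 1 * 1/4 = 25
    expect_equal(minimalInterference(5, 5)$reductionPercent, 25)
    # infinitely remote lysine does not interfere
    expect_lt(minimalInterference(4.3, 1e6)$reductionPercent, 1e-8)
})

test_that("force profile flags infeasible rows and handles an empty sweep", {
    empty <- forceProfile(4.3, r = numeric())
    expect_identical(nrow(empty), 0L)
    expect_identical(names(empty),
                     c("theta_deg", "r_angstrom", "f_attract_N",
                       "f_repel_axis_N", "f_net_N", "feasible"))
    prof <- forceProfile(4.3, r = c(8.1, -1, 5), theta = c(0, 0, 95))
    expect_identical(prof$feasible, c(TRUE, FALSE, FALSE))
    expect_true(all(is.na(prof$f_net_N[!prof$feasible])))
    # the single-point minimal sweep reproduces both reference forces
    one <- forceProfile(4.3, r = 8.1)
    expect_equal(one$f_attract_N, 2.489e-9, tolerance = 1e-3)
    expect_equal(one$f_repel_axis_N, 0.702e-9, tolerance = 1e-3)
})
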
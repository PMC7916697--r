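# Brute-force 2-D coordinate oracle for the interference triangle.
#
# Scenes are generated forwards: the lysine is placed explicitly in the
# plane, and (a, b, theta, phi) are measured from coordinates. The solver
# under test must then recover the Ca-Lys distance from those four numbers
# alone.

angleDeg <- function(u, v) {
    c_ <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(max(-1, min(1, c_))) * 180 / pi
}

# one random feasible scene; returns NULL when theta falls outside [0, 90)
randomScene <- function() {
    a <- runif(1, 2, 10)
    b <- runif(1, 0.5, 8)
    ca <- c(0, 0)
    d <- c(a, 0)
    psi <- runif(1, 0, 2 * pi)
    k <- d + b * c(cos(psi), sin(psi))
    r <- sqrt(sum((k - ca)^2))
    if (r < 1e-6) return(NULL)
    theta <- angleDeg(d - ca, k - ca)
    if (theta >= 89.999) return(NULL)
    phi <- angleDeg(ca - k, d - k)
    list(a = a, b = b, theta = theta, phi = phi, r = r, ca = ca, d = d, k = k)
}

feasibleScenes <- function(n) {
    out <- vector("list", n)
    got <- 0L
    while (got < n) {
        sc <- randomScene()
        if (!is.null(sc)) {
            got <- got + 1L
            out[[got]] <- sc
        }
    }
    out
}

# axial component of the exact Coulomb repulsion vector on Ca, projected on
# the Ca->Asp axis (positive = reduces the attraction)
projectedRepulsion <- function(scene, qCa = 2, qK = 1,
                               constants = coulombConstants()) {
    r <- scene$r
    fMag <- constants@ke * abs(qCa * qK) * constants@e^2 / (r * 1e-10)^2
    fVec <- fMag * (scene$ca - scene$k) / r      # repulsion pushes Ca away from K
    u <- (scene$d - scene$ca) / sqrt(sum((scene$d - scene$ca)^2))
    -sum(fVec * u)
}
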
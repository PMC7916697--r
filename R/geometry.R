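# Point-charge Coulomb model of the domain-III lysine interference.
#
# All distances enter in Angstrom and are converted to metres internally;
# charges are formal charges in elementary-charge units; forces are in N.

.ANGSTROM <- 1e-10

.chargeOf <- function(q) {
    if (is(q, "PointCharge")) q@charge else as.numeric(q)
}

# unsigned Coulomb magnitude for formal charges q1, q2 at distance d (A)
.coulombMag <- function(q1, q2, d, constants) {
    constants@ke * abs(q1 * q2) * constants@e^2 / (d * .ANGSTROM)^2
}

#' Default formal charges of the interference model
#'
#' Ca2+ carries +2, the aspartate side-chain carboxylate -1 and the lysine
#' ammonium +1 at physiological pH. The model is formal-charge only; no
#' partial charges.
#'
#' @return Named list of [PointCharge-class] objects `ca`, `asp`, `lys`.
#' @examples
#' defaultCharges()$lys
#' @export
defaultCharges <- function() {
    list(ca = pointCharge("Ca2+", +2),
         asp = pointCharge("Asp", -1),
         lys = pointCharge("Lys", +1))
}

#' Coulomb force between two point charges
#'
#' Magnitude of the electrostatic force between two formal charges at a
#' given separation, with the interaction type read off the sign of the
#' charge product.
#'
#' @param q1,q2 [PointCharge-class] objects (or bare numbers in
#'   elementary-charge units).
#' @param distance separation in Angstrom; must be positive.
#' @param constants a [CoulombConstants-class] object.
#' @return List with `force` (magnitude, N) and `interaction` ("attraction",
#'   "repulsion" or "none" for a zero charge).
#' @examples
#' ch <- defaultCharges()
#' coulombForce(ch$ca, ch$asp, 4.3)  # ~2.489e-9 N, attraction
#' @export
coulombForce <- function(q1, q2, distance, constants = coulombConstants()) {
    if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
        distance <= 0)
        stop("'distance' must be a single positive value in Angstrom")
    c1 <- .chargeOf(q1); c2 <- .chargeOf(q2)
    prod <- c1 * c2
    list(force = .coulombMag(c1, c2, distance, constants),
         interaction = if (prod < 0) "attraction"
                       else if (prod > 0) "repulsion" else "none")
}

#' Ca2+--lysine distance from the interference triangle
#'
#' Solves the triangle (Ca2+, Asp, Lys) for the Ca--Lys distance r given the
#' Ca--Asp distance a, the Asp--Lys distance b and the angle theta at the
#' Ca2+ vertex:
#' \deqn{r = a\cos\theta \pm \sqrt{b^2 - a^2\sin^2\theta}.}
#' The sign is selected by phi, the angle at the lysine vertex: phi < 90
#' degrees takes the far intersection (+), phi > 90 the near one (-), and
#' phi = 90 is the tangent case where the square root vanishes and
#' r = a cos(theta). When `validatePhi = TRUE` the supplied phi must also
#' agree numerically with the angle implied by the solved triangle.
#'
#' @param geom an [InterferenceGeometry-class] object.
#' @param validatePhi check phi against the embedding (law of cosines at the
#'   lysine vertex) to `phiTol` degrees and error on inconsistency.
#' @param phiTol tolerance in degrees for the phi consistency check.
#' @return Ca--Lys distance r in Angstrom.
#' @examples
#' lysineDistance(interferenceGeometry(a = 4.3, b = 3.8))  # 8.1
#' @export
lysineDistance <- function(geom, validatePhi = FALSE, phiTol = 0.5) {
    stopifnot(is(geom, "InterferenceGeometry"))
    validObject(geom)
    th <- geom@theta * pi / 180
    disc <- geom@b^2 - (geom@a * sin(th))^2
    if (disc < 0) {
        if (disc > -1e-12 * geom@b^2) disc <- 0
        else stop("infeasible geometry: b < a*sin(theta)")
    }
    s <- sqrt(disc)
    r <- if (geom@phi < 90) geom@a * cos(th) + s
         else if (geom@phi > 90) geom@a * cos(th) - s
         else geom@a * cos(th)
    if (r <= 0)
        stop(sprintf(
            "infeasible geometry: selected branch places the lysine at r = %.4g A (must be > 0)",
            r))
    if (validatePhi) {
        # law of cosines at the lysine vertex; side opposite is a
        cosPhi <- (r^2 + geom@b^2 - geom@a^2) / (2 * r * geom@b)
        cosPhi <- max(-1, min(1, cosPhi))
        phiImplied <- acos(cosPhi) * 180 / pi
        if (abs(phiImplied - geom@phi) > phiTol)
            stop(sprintf(
                "inconsistent geometry: phi = %.3g deg but the triangle implies %.3g deg",
                geom@phi, phiImplied))
    }
    r
}

#' Axial component of the lysine repulsion on Ca2+
#'
#' Projection of the Coulomb repulsion between Ca2+ and the lysine onto the
#' Ca->Asp axis: ke * qCa * qK * e^2 / r^2 * cos(theta).
#'
#' @param qCa,qK point charges for Ca2+ and lysine.
#' @param r Ca--Lys distance, Angstrom.
#' @param theta angle at Ca2+ between the Ca->Asp and Ca->Lys rays, degrees,
#'   in [0, 90).
#' @param constants a [CoulombConstants-class] object.
#' @return Axial force component in N.
#' @examples
#' ch <- defaultCharges()
#' repellentComponent(ch$ca, ch$lys, r = 8.1, theta = 0)  # ~0.702e-9 N
#' @export
repellentComponent <- function(qCa, qK, r, theta = 0,
                               constants = coulombConstants()) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
        stop("'r' must be a single positive distance in Angstrom")
    if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 90)
        stop("'theta' must lie in [0, 90) degrees")
    .coulombMag(.chargeOf(qCa), .chargeOf(qK), r, constants) *
        cos(theta * pi / 180)
}

#' Net axial force on Ca2+ towards the aspartate
#'
#' Attraction to the aspartate minus the axial component of the lysine
#' repulsion: F(Ca,D,K) = F(Ca,D) - F(Ca,K). Negative values mean the
#' lysine has reversed the net interaction into repulsion.
#'
#' @param geom an [InterferenceGeometry-class] object.
#' @param charges named list with `ca`, `asp`, `lys` point charges.
#' @param constants a [CoulombConstants-class] object.
#' @return Net force in N (positive = net attraction).
#' @examples
#' netAttraction(interferenceGeometry(a = 4.3, b = 3.8))  # ~1.787e-9 N
#' @export
netAttraction <- function(geom, charges = defaultCharges(),
                          constants = coulombConstants()) {
    r <- lysineDistance(geom)
    fAttr <- .coulombMag(.chargeOf(charges$ca), .chargeOf(charges$asp),
                         geom@a, constants)
    fRep <- repellentComponent(charges$ca, charges$lys, r, geom@theta, constants)
    fAttr - fRep
}

#' Minimal-interference configuration
#'
#' Evaluates the configuration in which the lysine perturbs the
#' Ca2+--aspartate attraction least: collinear on the far side of the
#' aspartate (theta = 0, r = a + b). Even there the lysine repulsion removes
#' a substantial fraction of the attraction; any closer placement removes
#' more.
#'
#' @param a Ca--Asp distance, Angstrom.
#' @param b Asp--Lys distance, Angstrom.
#' @param charges named list with `ca`, `asp`, `lys` point charges.
#' @param constants a [CoulombConstants-class] object.
#' @return List with `fAttract`, `fRepel` (N), `r` (Angstrom) and
#'   `reductionPercent` = 100 * fRepel / fAttract.
#' @examples
#' minimalInterference(4.3, 3.8)$reductionPercent  # ~28.2
#' @export
minimalInterference <- function(a, b, charges = defaultCharges(),
                                constants = coulombConstants()) {
    stopifnot(a > 0, b > 0)
    r <- a + b
    fAttr <- .coulombMag(.chargeOf(charges$ca), .chargeOf(charges$asp),
                         a, constants)
    fRep <- repellentComponent(charges$ca, charges$lys, r, 0, constants)
    list(fAttract = fAttr, fRepel = fRep, r = r,
         reductionPercent = 100 * fRep / fAttr)
}

#' Force profile over a sweep of lysine placements
#'
#' Tabulates the attraction, the axial lysine repulsion and the net axial
#' force for a sweep of Ca--Lys distances r (at fixed theta). Infeasible
#' sweep points (non-positive r, theta outside [0, 90)) are flagged per row
#' rather than raising.
#'
#' @param a Ca--Asp distance, Angstrom.
#' @param r numeric vector of Ca--Lys distances to evaluate, Angstrom.
#' @param theta angle(s) at the Ca2+ vertex, degrees; recycled against `r`.
#' @param charges named list with `ca`, `asp`, `lys` point charges.
#' @param constants a [CoulombConstants-class] object.
#' @return data.frame with columns theta_deg, r_angstrom, f_attract_N,
#'   f_repel_axis_N, f_net_N and feasible; suitable for CSV export.
#' @examples
#' forceProfile(4.3, r = seq(8.1, 4.0, by = -0.5))
#' @export
forceProfile <- function(a, r, theta = 0, charges = defaultCharges(),
                         constants = coulombConstants()) {
    stopifnot(a > 0)
    if (length(r) == 0L)
        return(data.frame(theta_deg = numeric(), r_angstrom = numeric(),
                          f_attract_N = numeric(), f_repel_axis_N = numeric(),
                          f_net_N = numeric(), feasible = logical()))
    n <- max(length(r), length(theta))
    r <- rep_len(r, n); theta <- rep_len(theta, n)
    fAttr <- .coulombMag(.chargeOf(charges$ca), .chargeOf(charges$asp),
                         a, constants)
    feasible <- is.finite(r) & r > 0 & is.finite(theta) & theta >= 0 & theta < 90
    fRep <- rep(NA_real_, n)
    fRep[feasible] <- vapply(which(feasible), function(i)
        repellentComponent(charges$ca, charges$lys, r[i], theta[i], constants),
        numeric(1))
    data.frame(theta_deg = theta, r_angstrom = r,
               f_attract_N = ifelse(feasible, fAttr, NA_real_),
               f_repel_axis_N = fRep,
               f_net_N = ifelse(feasible, fAttr - fRep, NA_real_),
               feasible = feasible)
}
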
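# Parameter constructors.  All base-model rate constants that the coupled
# gating scheme inherits from the rabbit ventricular LTCC Markov model are
# collected here, together with the calibrated constants of the release-unit
# and membrane formulations.  Units: time ms, voltage mV, Ca concentrations
# uM (Cao in mM), rates 1/ms, fluxes uM/ms, currents uA/uF (= A/F).

#' Parameters of the 7-state LTCC Markov model with cooperative gating
#'
#' Returns the full parameter set of the single-channel model: the Markov
#' rate constants of the 7-state scheme (two closed states C2/C1, the open
#' state O, Ca-inactivated I1Ca/I2Ca and voltage/Ba-inactivated I1Ba/I2Ba),
#' the GHK-type permeation constants, and the cooperative-gating parameters.
#'
#' Cooperativity multiplies the activation rate alpha (C2 to C1) by
#' \deqn{\gamma_1 = 1 + w_1\,\sigma(15(N_L/3 - po_x))\,\sigma(c_p - cp_x)}
#' and the opening rate r1 (C1 to O) by the analogous \eqn{\gamma_2} with
#' strength \eqn{w_2}, where \eqn{\sigma} is the logistic function,
#' \eqn{N_L} the number of open channels in the cluster and \eqn{c_p} the
#' cleft Ca in uM.  Both factors are 1 when \eqn{w = 0} and saturate at
#' \eqn{1 + w}.  \eqn{\gamma_2} is applied wherever r1 appears, including
#' the detailed-balance expressions for s2 and s2'.
#'
#' @param w1,w2 coupling strengths (dimensionless, >= 0).
#' @param po_x open-count sensitivity midpoint: the open-count logistic is
#'   centred at \eqn{N_L = 3\,po_x}.
#' @param cp_x cleft-Ca sensitivity midpoint (uM).
#' @param PCa single-channel permeability constant (current units).
#' @param gamma_i,gamma_o inner/outer activity coefficients.
#' @param Cao extracellular Ca (mM).
#' @param F,R,T physical constants (F in C/mmol so that \eqn{z = VF/RT} is
#'   dimensionless with V in mV).
#' @param tau_po open-probability time constant (ms).
#' @param r1,r2 opening/closing rates C1-O (1/ms).
#' @param s1p,k1p,k2p,k2 rate constants of the inactivation branches (1/ms).
#' @param TBa voltage-inactivation recovery floor (ms).
#' @param cpt half-saturation of the cleft-Ca sensor f(c_p) (uM).
#' @param cpminus half-saturation of the Ca-inactivation recovery time
#'   T_Ca (uM).
#' @return A named list of class `ltcc_params`.
#' @export
#' @examples
#' p <- ltcc_params(w1 = 0, w2 = 0)  # uncoupled channel
ltcc_params <- function(w1 = 5, w2 = 1.3, po_x = 1 / 3, cp_x = 3,
                        PCa = 0.00054, gamma_i = 0.341, gamma_o = 0.341,
                        Cao = 1.8, F = 96.485, R = 8.314, T = 308,
                        tau_po = 1, r1 = 0.3, r2 = 3, s1p = 0.00195,
                        k1p = 0.00413, k2p = 0.00224, k2 = 1.03615e-4,
                        TBa = 450, cpt = 3, cpminus = 40) {
  stopifnot(w1 >= 0, w2 >= 0, tau_po > 0, r1 > 0, r2 > 0, T > 0,
            cpt > 0, cpminus > 0)
  structure(list(
    w1 = w1, w2 = w2, po_x = po_x, cp_x = cp_x,
    PCa = PCa, gamma_i = gamma_i, gamma_o = gamma_o, Cao = Cao,
    F = F, R = R, T = T,
    tau_po = tau_po, r1 = r1, r2 = r2, s1p = s1p, k1p = k1p, k2p = k2p,
    k2 = k2, TBa = TBa, cpt = cpt, cpminus = cpminus
  ), class = "ltcc_params")
}

#' Geometry of the CRU lattice
#'
#' The default geometry is the full-cell lattice of 65 x 27 x 11 = 19,305
#' Ca release units at 1.84 um longitudinal and 0.9 um transverse spacing,
#' each CRU holding 100 RyRs and an LTCC cluster whose size is drawn from a
#' rounded Gaussian with mean 10 and sd 3, clamped to [1, 25].  Reduced
#' lattices (e.g. 8 x 8 x 4) are used for desk-scale simulation.
#'
#' @param nx,ny,nz lattice dimensions (longitudinal, transverse, transverse).
#' @param dx_long,dx_trans CRU separations (um), metadata only.
#' @param cluster_mean,cluster_sd Gaussian cluster-size parameters.
#' @param cluster_min,cluster_max clamp bounds for the cluster size.
#' @return A named list of class `cell_geometry`.
#' @export
cell_geometry <- function(nx = 65, ny = 27, nz = 11, dx_long = 1.84,
                          dx_trans = 0.9, cluster_mean = 10, cluster_sd = 3,
                          cluster_min = 1, cluster_max = 25) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, cluster_min >= 1,
            cluster_max >= cluster_min, cluster_max <= 25)
  structure(list(nx = nx, ny = ny, nz = nz, dx_long = dx_long,
                 dx_trans = dx_trans, cluster_mean = cluster_mean,
                 cluster_sd = cluster_sd, cluster_min = cluster_min,
                 cluster_max = cluster_max),
            class = "cell_geometry")
}

#' Parameters of the stochastic release-unit / whole-cell model
#'
#' Collects every constant of the stochastic cell: the nested LTCC cluster
#' parameters, the 4-state RyR cluster (closed -> open -> inactivated ->
#' refractory -> closed, opening rate
#' \eqn{K_u\,\phi(c_{JSR})\,c_p^2/(c_p^2+K_{cp}^2)}), the five-compartment
#' Ca fluxes with their volume ratios and diffusive couplings, instantaneous
#' (calmodulin, SR membrane, calsequestrin) and time-dependent (troponin C)
#' buffering, and the compact sarcolemmal membrane model (Luo-Rudy style
#' INa/IK/IK1/IKp plus NCX, background Ca flux and sarcolemmal Ca pump
#' evaluated per CRU).
#'
#' The RyR opening constants are calibrated so that an isolated spark
#' (clamped cleft-Ca pulse) recruits 5--10 of the 100 RyRs of a CRU; the
#' LTCC flux and membrane conductances are calibrated to give a resting
#' potential near -86 mV and physiological Ca transients.
#'
#' @param ltcc LTCC cluster parameters, see [ltcc_params()].
#' @param coupled logical; if `FALSE`, `w1` and `w2` are forced to 0 (all
#'   other parameters untouched), giving the exactly uncoupled model.
#' @param ... named overrides of any constant in the returned list.
#' @return A named list of class `cell_params`.
#' @export
#' @examples
#' p_off <- cell_params(coupled = FALSE)
#' p_on  <- cell_params()
cell_params <- function(ltcc = ltcc_params(), coupled = TRUE, ...) {
  if (!coupled) {
    ltcc$w1 <- 0
    ltcc$w2 <- 0
  }
  p <- list(
    ltcc = ltcc,
    # RyR cluster
    Ku = 0.09, Kcp = 15, Kjsr = 650, hjsr = 10,
    tau_o = 2, tau_i = 60, tau_rr = 200, n_ryr = 100L,
    # luminal (depletion-driven) closed-state inactivation: release
    # refractoriness carried across beats
    Ku_i = 0.01, Kjsr_i = 500, hjsr_i = 10,
    # release and uptake
    g_rel = 50, flux_scale = 600,
    vup = 0.4, Kup = 0.5,
    # NCX, background, sarcolemmal pump (submembrane flux units)
    vncx = 2000, eta = 0.35, ksat = 0.1, KmNa = 87.5, KmCa = 1.38,
    Nai = 10, Nao = 136,
    jcab = 0.015, vpmca = 0.1, Kpmca = 0.5,
    # relative compartment volumes (v_i = 1)
    vs = 0.1, vp = 0.03, vjsr = 0.008, vnsr = 0.08,
    # exchange / diffusion time constants (ms)
    tau_si = 2, tau_p = 0.1, tau_tr = 50,
    tau_ci_L = 3, tau_ci_T = 1.5, tau_cs_L = 3, tau_cs_T = 1.5,
    tau_nsr_L = 20, tau_nsr_T = 10,
    # buffering
    Bcam = 24, Kcam = 7, Bsr = 47, Ksr = 0.6, Bcsqn = 10000, Kcsqn = 600,
    BT = 70, kon = 0.0327, koff = 0.0196,
    # membrane
    gna = 16, gk = 0.3, gk1 = 0.6, gkp = 0.018, gbk = 0.01,
    ENa = 54.4, alpha_conv = 8,
    # initial values
    ci0 = 0.1, cs0 = 0.1, cp0 = 0.1, cnsr0 = 800, cjsr0 = 800, V0 = -86
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown cell_params field(s): ", paste(unknown, collapse = ", "))
    p <- modifyList(p, dots)
  }
  structure(p, class = "cell_params")
}

#' Parameters of the deterministic ionic model
#'
#' Whole-cell AP model with Shiferaw-type Ca cycling.  Cooperative gating
#' enters through
#' \deqn{\gamma_d = 1 + w\,\sigma(15(po_{Ca} - po_x))\,\sigma(c_s - cs_x)}
#' multiplying the activation rate \eqn{\alpha_d} of the L-type d gate,
#' with \eqn{po_{Ca} = d f f_{Ca}} the channel open probability.  The scale
#' of the coupling term is exposed as `w_scale` (default 1; the bounded form
#' \eqn{1 + 0.01 w} is obtained with `w_scale = 0.01`, but is too weak by
#' two orders of magnitude to produce the current amplification and
#' activation shift that motivate the model -- see the package vignette).
#'
#' Key dynamical controls: `tau_f` (recovery time constant of voltage
#' inactivation, ms) steepens APD restitution, `u` (high-load slope of the
#' piecewise-linear SR release-load function Q) destabilises Ca cycling, and
#' `gamma` (exponent of Ca-dependent inactivation
#' \eqn{f_{Ca,\infty} = 1/(1+(c_s/\hat c_s)^\gamma)}) sets the sign of the
#' Ca-to-voltage coupling: 0.7 gives positive, 1.5 negative coupling.
#'
#' @param tau_f f-gate recovery time constant (ms).
#' @param u high-load slope of the SR release function Q (per paced beat;
#'   the low-load slope is 1).
#' @param gamma Ca-inactivation exponent.
#' @param w coupling strength (dimensionless, >= 0).
#' @param ... named overrides of any constant in the returned list.
#' @return A named list of class `ionic_params`.
#' @export
#' @examples
#' p <- ionic_params(tau_f = 45, u = 3, gamma = 0.7, w = 0)
ionic_params <- function(tau_f = 45, u = 3, gamma = 0.7, w = 0, ...) {
  stopifnot(tau_f > 0, w >= 0)
  p <- list(
    # sarcolemmal conductances (uA/uF per mV)
    gna = 16, gkr = 0.06, gks = 0.1, gto = 0.15, gk1 = 0.35, gkp = 0.008,
    gkr_scale = 1,
    # LTCC
    gca = 0.01, tau_d_scale = 14, tau_f = tau_f, tau_fca = 5,
    gamma = gamma, cs_hat = 1.8,
    # cooperative gating
    w = w, w_scale = 8, po_x = 0.1, cs_x = 1.5,
    # NCX
    vncx = 220, eta = 0.35, ksat = 0.1, KmNa = 87.5, KmCa = 1.38,
    Nai = 10, Nao = 136, Cao = 1.8,
    # physical constants / reversal potentials
    F = 96.485, R = 8.314, T = 308, ENa = 54.4, EK = -87,
    # Ca cycling
    u = u, g_rel = 0.001, tau_r = 30, tau_a = 100, tau_s = 10, vi_vs = 10,
    q_floor = 50, q_knee = 80,
    vup = 0.45, Kup = 0.5, jcab = 0.02016, vpmca = 0.05, Kpmca = 0.5,
    # instantaneous buffers (calmodulin, SR membrane, troponin C)
    Bcam = 24, Kcam = 7, Bsr = 47, Ksr = 0.6, BT = 70, KT = 0.6,
    Bhi = 300, Khi = 30,
    # flux-to-current conversion (uA/uF per uM/ms univalent flux)
    alpha_conv = 8,
    # stimulus
    stim_amp = -40, stim_dur = 1
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown ionic_params field(s): ", paste(unknown, collapse = ", "))
    p <- modifyList(p, dots)
  }
  structure(p, class = "ionic_params")
}
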
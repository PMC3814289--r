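# model_fixtures: bundled, programmatically constructed models covering the
# package's test and demonstration surface.

#' Michaelis-Menten reaction mechanism (open system)
#'
#' Substrate S enters at constant rate, binds enzyme E to a complex SE,
#' which either dissociates or converts to product P; P leaves the system.
#' Five irreversible mass-action reactions over species S, SE, P, E with one
#' conserved moiety (total enzyme `[E] + [SE] = beta`). With all rate
#' constants at 1 and `beta = 10` the steady state densities are
#' `(S, SE, P, E) = (2/9, 1, 1, 9)`.
#'
#' @param k1,k2,k3,k4,k5 Positive rate constants of influx, binding,
#'   dissociation, catalysis and product efflux.
#' @param beta Total enzyme density (free + complexed); a physical positive
#'   steady state needs `beta > k1 / k4` (warned otherwise).
#' @param omega System size (particles per density unit).
#' @return A [reaction_network()].
#' @export
#' @examples
#' lna(michaelis_menten())$C
michaelis_menten <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1,
                             beta = 10, omega = 100) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, k4 > 0, k5 > 0, beta > 0)
  if (beta <= k1 / k4) {
    warning("beta <= k1/k4: the deterministic steady state is non-physical")
    # no positive steady state exists; start from a neutral interior state
    x2 <- beta / 2
    x1 <- 1
  } else {
    # start at the deterministic steady state (E* = beta - k1/k4)
    x2 <- k1 / k4
    x1 <- (k1 * k3 + k1 * k4) / (k2 * k4 * (beta - x2))
  }
  reaction_network(
    species = data.frame(id = c("S", "SE", "P", "E"),
                         name = c("substrate", "enzyme-substrate complex",
                                  "product", "free enzyme"),
                         initial = c(x1, x2, k1 / k5, beta - x2)),
    reactions = list(
      reaction("influx", NULL, c(S = 1), mass_action("k1")),
      reaction("binding", c(S = 1, E = 1), c(SE = 1), mass_action("k2")),
      reaction("dissociation", c(SE = 1), c(S = 1, E = 1), mass_action("k3")),
      reaction("catalysis", c(SE = 1), c(P = 1, E = 1), mass_action("k4")),
      reaction("efflux", c(P = 1), NULL, mass_action("k5"))
    ),
    parameters = c(k1 = unname(k1), k2 = unname(k2), k3 = unname(k3),
                   k4 = unname(k4), k5 = unname(k5)),
    system_size = omega, name = "michaelis_menten")
}

#' Birth-death process
#'
#' `0 -> X` at constant rate `k`, `X -> 0` at rate `d * x`. The stationary
#' law is Poisson with mean `omega * k / d`, so the LNA is exact here:
#' variance equals mean and the Fano factor is 1.
#'
#' @param k,d Positive birth and death rate constants.
#' @param omega System size.
#' @return A [reaction_network()].
#' @export
birth_death <- function(k = 5, d = 0.5, omega = 10) {
  stopifnot(k > 0, d > 0)
  reaction_network(
    species = data.frame(id = "X", initial = k / d),
    reactions = list(
      reaction("birth", NULL, c(X = 1), mass_action("k")),
      reaction("death", c(X = 1), NULL, mass_action("d"))
    ),
    parameters = c(k = unname(k), d = unname(d)),
    system_size = omega, name = "birth_death")
}

#' Open linear chain
#'
#' `0 -> X1 -> X2 -> ... -> Xn -> 0` with constant influx and first-order
#' steps. Open monomolecular networks have a product-form Poisson
#' stationary law: the LNA covariance is diagonal with variance equal to
#' mean for every species.
#'
#' @param influx Constant influx rate.
#' @param rates First-order rate constants of the `length` transfer/exit
#'   steps (recycled).
#' @param length Number of species (>= 2).
#' @param omega System size.
#' @return A [reaction_network()].
#' @export
linear_chain <- function(influx = 5, rates = 1, length = 3, omega = 10) {
  stopifnot(length >= 2, influx > 0, all(rates > 0))
  rates <- rep_len(rates, length)
  ids <- paste0("X", seq_len(length))
  rx <- list(reaction("influx", NULL, stats::setNames(1, ids[1]),
                      mass_action("k_in")))
  for (i in seq_len(length)) {
    prod <- if (i < length) stats::setNames(1, ids[i + 1]) else NULL
    rx[[i + 1]] <- reaction(paste0("step", i), stats::setNames(1, ids[i]),
                            prod, mass_action(paste0("k", i)))
  }
  reaction_network(
    species = data.frame(id = ids, initial = influx / rates),
    reactions = rx,
    parameters = stats::setNames(c(unname(influx), unname(rates)),
                                 c("k_in", paste0("k", seq_len(length)))),
    system_size = omega, name = "linear_chain")
}

#' MAPK (ERK) signalling cascade
#'
#' Three-tier kinase cascade with saturating (Michaelis-Menten type)
#' kinetics and negative feedback of doubly phosphorylated MAPK on the
#' first activation step, after Kholodenko's generic ERK model
#' (BioModels BIOMD0000000010). Species are MKKK/MKKK_P, MKK/MKK_P/MKK_PP
#' and MAPK/MAPK_P/MAPK_PP in nM; time in s. Each tier total is conserved
#' (Lambda = 3, K = 5). With the default feedback constant `ki = 45` the
#' steady state is stable; the original model (`ki = 9`) oscillates.
#'
#' @param ki Inhibition constant of the negative feedback (nM).
#' @param v_cell Cell volume in litres; the system size is
#'   `1e-9 * N_A * v_cell` particles per nM (about 6.022 at 1e-14 l).
#' @param v2 Vmax of MKKK_P dephosphorylation (the activity of the MKKK
#'   phosphatase), nM/s.
#' @param k4 Rate constant of the second MKK phosphorylation step, 1/s.
#' @return A [reaction_network()].
#' @export
#' @examples
#' net <- erk_cascade()
#' reduce_network(net)
erk_cascade <- function(ki = 45, v_cell = 1e-14, v2 = 0.25, k4 = 0.025) {
  omega <- 1e-9 * 6.02214076e23 * unname(v_cell)  # particles per nM
  reaction_network(
    species = data.frame(
      id = c("MKKK", "MKKK_P", "MKK", "MKK_P", "MKK_PP",
             "MAPK", "MAPK_P", "MAPK_PP"),
      initial = c(90, 10, 280, 10, 10, 280, 10, 10)),
    reactions = list(
      reaction("mkkk_act", c(MKKK = 1), c(MKKK_P = 1),
               rate_expr("V1 * MKKK / ((1 + (MAPK_PP / Ki)^n) * (K1 + MKKK))")),
      reaction("mkkk_deact", c(MKKK_P = 1), c(MKKK = 1),
               rate_expr("V2 * MKKK_P / (K2 + MKKK_P)")),
      reaction("mkk_p1", c(MKK = 1), c(MKK_P = 1),
               rate_expr("k3 * MKKK_P * MKK / (K3 + MKK)")),
      reaction("mkk_p2", c(MKK_P = 1), c(MKK_PP = 1),
               rate_expr("k4 * MKKK_P * MKK_P / (K4 + MKK_P)")),
      reaction("mkk_dp1", c(MKK_PP = 1), c(MKK_P = 1),
               rate_expr("V5 * MKK_PP / (K5 + MKK_PP)")),
      reaction("mkk_dp2", c(MKK_P = 1), c(MKK = 1),
               rate_expr("V6 * MKK_P / (K6 + MKK_P)")),
      reaction("mapk_p1", c(MAPK = 1), c(MAPK_P = 1),
               rate_expr("k7 * MKK_PP * MAPK / (K7 + MAPK)")),
      reaction("mapk_p2", c(MAPK_P = 1), c(MAPK_PP = 1),
               rate_expr("k8 * MKK_PP * MAPK_P / (K8 + MAPK_P)")),
      reaction("mapk_dp1", c(MAPK_PP = 1), c(MAPK_P = 1),
               rate_expr("V9 * MAPK_PP / (K9 + MAPK_PP)")),
      reaction("mapk_dp2", c(MAPK_P = 1), c(MAPK = 1),
               rate_expr("V10 * MAPK_P / (K10 + MAPK_P)"))
    ),
    parameters = c(V1 = 2.5, Ki = unname(ki), n = 1, K1 = 10,
                   V2 = unname(v2), K2 = 8,
                   k3 = 0.025, K3 = 15, k4 = unname(k4), K4 = 15,
                   V5 = 0.75, K5 = 15, V6 = 0.75, K6 = 15,
                   k7 = 0.025, K7 = 15, k8 = 0.025, K8 = 15,
                   V9 = 0.5, K9 = 15, V10 = 0.5, K10 = 15),
    system_size = omega, name = "erk_cascade")
}

#' Synthetic two-branch signalling cascade
#'
#' A mass-action stand-in for two-branch MAPK topologies (such as the
#' MKK3/MKK6 branches upstream of p38): a fluctuating active receptor R
#' activates two parallel kinases A and B; both active forms phosphorylate
#' a shared downstream kinase D, whose active form phosphorylates the
#' output species OUT. Each tier has a first-order deactivation
#' ("phosphatase") step and a conserved active+inactive total.
#'
#' @param s,dr Receptor synthesis and decay rates.
#' @param ka,kb Activation rate constants of the two branches.
#' @param ia,ib Deactivation rate constants of the two branches.
#' @param kd,id_ Activation/deactivation rate constants of the shared kinase.
#' @param ko,io Activation/deactivation rate constants of the output.
#' @param omega System size.
#' @return A [reaction_network()] with 8 species and 10 reactions.
#' @export
two_branch_cascade <- function(s = 2, dr = 1, ka = 0.5, kb = 0.5,
                               ia = 1, ib = 1, kd = 0.2, id_ = 1,
                               ko = 0.2, io = 1, omega = 50) {
  reaction_network(
    species = data.frame(
      id = c("R", "A", "A_star", "B", "B_star", "D", "D_star", "OUT_star"),
      initial = c(s / dr, 4, 1, 4, 1, 4, 1, 1)),
    reactions = list(
      reaction("r_on", NULL, c(R = 1), mass_action("s")),
      reaction("r_off", c(R = 1), NULL, mass_action("dr")),
      reaction("a_act", c(R = 1, A = 1), c(R = 1, A_star = 1),
               mass_action("ka")),
      reaction("a_deact", c(A_star = 1), c(A = 1), mass_action("ia")),
      reaction("b_act", c(R = 1, B = 1), c(R = 1, B_star = 1),
               mass_action("kb")),
      reaction("b_deact", c(B_star = 1), c(B = 1), mass_action("ib")),
      reaction("d_act_a", c(A_star = 1, D = 1), c(A_star = 1, D_star = 1),
               mass_action("kd")),
      reaction("d_act_b", c(B_star = 1, D = 1), c(B_star = 1, D_star = 1),
               mass_action("kd")),
      reaction("d_deact", c(D_star = 1), c(D = 1), mass_action("id_")),
      reaction("out_act", c(D_star = 1), c(D_star = 1, OUT_star = 1),
               mass_action("ko")),
      reaction("out_deact", c(OUT_star = 1), NULL, mass_action("io"))
    ),
    parameters = vapply(list(s = s, dr = dr, ka = ka, kb = kb, ia = ia,
                             ib = ib, kd = kd, id_ = id_, ko = ko, io = io),
                        unname, 0),
    system_size = omega, name = "two_branch_cascade")
}
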
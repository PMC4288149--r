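# Phenomenological force field. Bonded DNA terms (harmonic stretch,
# Kratky-Porod bending, harmonic twist through the patch frames plus a
# patch-tangent alignment term), WCA excluded volume, the helical-path
# site attraction with cosine angular modulation, the isotropic
# nanoparticle well, and the capped soft-core repulsion used during
# topo-II windows.

KB_J <- 1.380649e-23

#' Force-field parameters
#'
#' All energies in kBT, lengths in nm. The bending stiffness is calibrated
#' so that an equilibrium chain of `sigma_dna` beads has persistence
#' length `lp_target` under the discrete Kratky-Porod statistics
#' (`bend_k = 1 / (1 - exp(-sigma/lp))`, which for 2.5 nm beads and a
#' 50 nm target gives 20.5 kBT; the naive continuum estimate lp/sigma = 20
#' would under-shoot the persistence length by about 2.5 percent). The
#' per-joint twist stiffness maps the torsional rigidity
#' `C = 3e-19 erg cm` through `twist_k = C / (kBT sigma)` in kBT/rad^2.
#'
#' @param sigma_dna DNA bead diameter, nm (2.5 nm = DNA thickness).
#' @param lp_target bending persistence length, nm.
#' @param torsional_C torsional rigidity in erg cm.
#' @param temperature Kelvin, used only to convert `torsional_C`.
#' @param bond_k bond stiffness, kBT/nm^2.
#' @param bend_k Kratky-Porod bending constant, kBT; derived from
#'   `lp_target` when NULL.
#' @param twist_k per-joint twist stiffness, kBT/rad^2; derived from
#'   `torsional_C` when NULL.
#' @param align_k patch-tangent alignment stiffness, kBT.
#' @param eps_rep WCA repulsion scale, kBT.
#' @param eps_site depth of one octamer site / DNA patch contact, kBT.
#' @param eps_nano depth of the isotropic nanoparticle well per DNA bead,
#'   kBT (4.3 reproduces two-turn wrapping of an isolated sphere).
#' @param eps_boost multiplier applied to `eps_site` in the
#'   increased-affinity twist-offset variant.
#' @param softcore_cap maximum DNA-DNA repulsion during a topo-II window,
#'   kBT (small enough that thermal motion crosses strands).
#' @param site_capture capture radius of a binding site, nm.
#' @param site_ang_cos cosine cutoff of the patch angular modulation
#'   (0.5 = 60 degree cone, giving roughly a 30 degree half-width at
#'   half-maximum).
#' @param core_diam core body diameter, nm.
#' @param path_radius,path_pitch wrap-path geometry, nm (see
#'   [core_geometry()]).
#' @param nano_well_w width of the nanoparticle attraction well, nm.
#' @param slit_k flattening-wall stiffness, kBT/nm^2.
#' @param confine_R radius of a soft spherical confinement centred at the
#'   origin, nm (negative = none). Reconstitution protocols set it to the
#'   coil size so that unbound cores stay at a realistic concentration
#'   instead of escaping to infinite dilution.
#' @param confine_k confinement stiffness, kBT/nm^2.
#' @param bond_r0 bond rest length, nm (defaults to `sigma_dna`).
#' @return list of class `ff_params`.
#' @export
ff_params <- function(sigma_dna = 2.5, lp_target = 50,
                      torsional_C = 3e-19, temperature = 300,
                      bond_k = 10, bend_k = NULL, twist_k = NULL,
                      align_k = 30, eps_rep = 4, eps_site = 10,
                      eps_nano = 4.3, eps_boost = 1.3, softcore_cap = 2,
                      site_capture = 1.5, site_ang_cos = 0.5,
                      core_diam = 6.75, path_radius = 4.2, path_pitch = 3.0,
                      nano_well_w = 2.5, slit_k = 5, confine_R = -1,
                      confine_k = 0.5, bond_r0 = sigma_dna) {
  if (is.null(bend_k)) {
    # The patch-tangent alignment springs act as two stiffness-align_k
    # springs in series between consecutive bonds, adding align_k/2 of
    # effective Kratky-Porod stiffness; the explicit bend term supplies
    # the remainder of the discrete-chain calibration target.
    bend_eff <- 1 / (1 - exp(-sigma_dna / lp_target))
    bend_k <- bend_eff - align_k / 2
    if (bend_k < 0)
      stop("align_k too large for the requested persistence length",
           call. = FALSE)
  }
  if (is.null(twist_k)) {
    kT <- KB_J * temperature                  # J
    # erg cm -> J m (1e-9) -> /kT -> m -> nm (1e9): factors cancel
    C_nm <- torsional_C / kT
    twist_k <- C_nm / sigma_dna
  }
  p <- list(sigma_dna = sigma_dna, lp_target = lp_target,
            torsional_C = torsional_C, temperature = temperature,
            bond_k = bond_k, bond_r0 = bond_r0, bend_k = bend_k,
            twist_k = twist_k, align_k = align_k, eps_rep = eps_rep,
            eps_site = eps_site, eps_nano = eps_nano, eps_boost = eps_boost,
            softcore_cap = softcore_cap, site_capture = site_capture,
            site_ang_cos = site_ang_cos, core_diam = core_diam,
            path_radius = path_radius, path_pitch = path_pitch,
            nano_well_w = nano_well_w, slit_k = slit_k,
            confine_R = confine_R, confine_k = confine_k)
  stopifnot(all(vapply(p[c("bond_k", "bend_k", "twist_k", "align_k",
                           "eps_rep")], function(x) x >= 0, TRUE)),
            is.finite(softcore_cap))
  structure(p, class = c("ff_params", "list"))
}

#' @export
print.ff_params <- function(x, ...) {
  cat("<ff_params>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

# internal: full argument list for the C++ kernels
ffc <- function(state, params, softcore = FALSE, twist_scale = 1,
                eps_mult = 1, slit_gap = -1) {
  a <- state_arrays(state)
  c(list(pos = a$pos, quat = a$quat, chain = a$chain, circ = a$circ,
         cpos = a$cpos, cquat = a$cquat, ckind = a$ckind,
         site_loc = a$site_loc, site_dir = a$site_dir, active = a$active,
         params = unclass(params)),
    list(softcore = softcore, twist_scale = twist_scale,
         eps_mult = eps_mult, slit_gap = slit_gap))
}

#' Bonded energy and exact forces/torques of a chain
#'
#' Stretch + Kratky-Porod bend + harmonic twist (+ the patch alignment
#' term that couples frames to the backbone). Forces and torques are exact
#' analytic gradients, validated against finite differences in the test
#' suite.
#'
#' @param chain a [dna_chain()].
#' @param params [ff_params()].
#' @return list with `energy`, `terms`, `forces` (n x 3, kBT/nm) and
#'   `torques` (n x 3, kBT).
#' @export
bonded_energy_forces <- function(chain, params = ff_params()) {
  st <- system_state(chain)
  r <- do.call(cpp_forces, ffc(st, params))
  list(energy = sum(r$terms[c("bond", "bend", "align", "twist")]),
       terms = r$terms[c("bond", "bend", "align", "twist")],
       forces = r$f_bead, torques = r$t_bead)
}

#' Non-bonded energy and forces/torques of a system
#'
#' DNA-DNA and DNA-core excluded volume, site-patch attraction (octamers),
#' isotropic attraction (nanoparticles). With `softcore = TRUE` the
#' DNA-DNA repulsion is replaced by a finite-cap cosine potential so that
#' thermal motion can pass strands through each other (topo-II emulation).
#'
#' @param state a [system_state()].
#' @param params [ff_params()].
#' @param softcore logical.
#' @param eps_mult multiplier on `eps_site` (affinity boost variant).
#' @return list with `energy`, `terms`, and force/torque matrices for
#'   beads and cores.
#' @export
pair_energy_forces <- function(state, params = ff_params(),
                               softcore = FALSE, eps_mult = 1) {
  r <- do.call(cpp_forces, ffc(state, params, softcore = softcore,
                               eps_mult = eps_mult))
  keep <- c("rep", "soft", "site", "nano")
  list(energy = sum(r$terms[keep]), terms = r$terms[keep],
       f_bead = r$f_bead, t_bead = r$t_bead,
       f_core = r$f_core, t_core = r$t_core)
}

#' Total energy and gradients (all terms)
#' @inheritParams pair_energy_forces
#' @param twist_scale scale factor on the twist stiffness (topo-I window).
#' @param slit_gap flattening slit gap in nm, or negative for none.
#' @export
energy_forces <- function(state, params = ff_params(), softcore = FALSE,
                          twist_scale = 1, eps_mult = 1, slit_gap = -1) {
  do.call(cpp_forces, ffc(state, params, softcore, twist_scale, eps_mult,
                          slit_gap))
}

#' Bead-site contact table
#'
#' One row per (bead, core, site) contact within the site capture radius,
#' with the distance, the patch/site angular cosine and the contact energy
#' in kBT. This is the raw material for the binding criterion used by
#' [wrapped_bp()].
#'
#' @param state a [system_state()].
#' @param params [ff_params()].
#' @param eps_mult multiplier on `eps_site`.
#' @return data.frame with columns bead, core, site, dist, cos_beta,
#'   energy (bead/core/site indices are 1-based and bead indices are
#'   global across chains).
#' @export
site_contacts <- function(state, params = ff_params(), eps_mult = 1) {
  a <- state_arrays(state)
  m <- cpp_site_pairs(a$pos, a$quat, a$cpos, a$cquat, a$ckind,
                      a$site_loc, a$site_dir, a$active,
                      unclass(params), eps_mult)
  as.data.frame(m)
}
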
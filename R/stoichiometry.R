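#' Species terms and transport cycles
#'
#' A transport cycle is a list of species moved per cycle, each with a
#' stoichiometric coefficient (positive for co-transport; a negative
#' coefficient denotes antiport), a signed charge, and concentrations on the
#' two sides of the membrane. Concentrations may be in any unit, provided the
#' same unit is used on both sides of a given species: only ratios enter the
#' thermodynamics.
#'
#' @param name species name.
#' @param coeff stoichiometric coefficient per cycle (nonzero).
#' @param charge signed charge, elementary units.
#' @param conc_in,conc_out concentrations inside / outside (> 0, same unit).
#' @return `species_term`: a one-row data frame.
#' @export
species_term <- function(name, coeff, charge, conc_in, conc_out) {
  if (coeff == 0) stop("coeff must be nonzero")
  if (conc_in <= 0 || conc_out <= 0) stop("concentrations must be positive")
  data.frame(name = name, coeff = coeff, charge = charge,
             conc_in = conc_in, conc_out = conc_out)
}

#' @param ... `species_term` rows.
#' @param slope_mV_per_decade Nernst slope, mV per tenfold ratio. The default
#'   60 (rather than 59.16 at 25 C) matches the convention in which a 20-fold
#'   gradient across a single net charge gives 78.06 mV.
#' @return `transport_cycle` object.
#' @rdname species_term
#' @export
transport_cycle <- function(..., slope_mV_per_decade = 60) {
  terms <- do.call(rbind, list(...))
  if (slope_mV_per_decade <= 0) stop("slope must be positive")
  structure(list(terms = terms, slope = slope_mV_per_decade),
            class = "transport_cycle")
}

#' @export
print.transport_cycle <- function(x, ...) {
  cat("<transport_cycle> z_net =", net_charge(x), "\n")
  print(x$terms)
  invisible(x)
}

#' Net charge moved per cycle
#' @param cycle a [transport_cycle()].
#' @return sum of coeff * charge.
#' @export
net_charge <- function(cycle) sum(cycle$terms$coeff * cycle$terms$charge)

#' A sodium/aspartate co-transport cycle
#'
#' Convenience constructor for the n Na+ : 1 substrate(-1) cycle of
#' glutamate-transporter homolog assays: sodium at equal concentration on
#' both sides (so only the substrate gradient contributes chemically) and the
#' substrate at `asp_in` inside versus `asp_out` outside.
#'
#' @param n_na sodium ions co-transported per substrate.
#' @param na_mM sodium concentration on both sides, mM.
#' @param asp_in,asp_out substrate concentrations, any common unit
#'   (defaults 10 and 0.5 uM: a 20-fold outward gradient).
#' @param slope Nernst slope, mV/decade.
#' @return A [transport_cycle()].
#' @export
na_asp_cycle <- function(n_na = 3, na_mM = 200, asp_in = 10, asp_out = 0.5,
                         slope = 60) {
  transport_cycle(
    species_term("Na+", n_na, +1, na_mM, na_mM),
    species_term("L-asp", 1, -1, asp_in, asp_out),
    slope_mV_per_decade = slope)
}

#' Reversal (equilibrium) potential of a coupled transport cycle
#'
#' The membrane potential (inside minus outside, mV) at which one full cycle
#' has zero net free energy:
#' `V_rev = -(s / z_net) * sum_i coeff_i * log10(conc_in_i / conc_out_i)`.
#' For sodium at equal concentration on both sides and a single substrate of
#' charge -1 with a c_in/c_out gradient, this reduces to
#' `-s * log10(c_in/c_out) / (n - 1)` for n sodium ions per cycle.
#'
#' @param cycle a [transport_cycle()].
#' @return potential in mV.
#' @export
reversal_potential <- function(cycle) {
  z <- net_charge(cycle)
  if (abs(z) < 1e-12)
    stop("cycle is electroneutral; no finite reversal potential")
  t <- cycle$terms
  -(cycle$slope / z) * sum(t$coeff * log10(t$conc_in / t$conc_out))
}

#' Predict flux direction under an applied membrane potential
#'
#' The electrochemical driving free energy of one forward (influx) cycle is
#' `dG = z_net * F * (V_applied - V_rev)`; the cycle runs forward (influx)
#' when `dG < 0`, backward (efflux) when `dG > 0`, and is at equilibrium when
#' `|V_applied - V_rev|` is below `tol_mV`.
#'
#' @param cycle a [transport_cycle()].
#' @param applied_potential mV, inside minus outside.
#' @param tol_mV equilibrium half-width (default 0.5 mV).
#' @return list with `direction` (`"influx"`, `"efflux"` or
#'   `"equilibrium"`), `reversal_mV`, and `delta_G_kJ_per_cycle_mol` for the
#'   influx direction (F = 96.485 kJ/(mol V)).
#' @export
flux_direction <- function(cycle, applied_potential, tol_mV = 0.5) {
  vrev <- reversal_potential(cycle)
  z <- net_charge(cycle)
  dv <- applied_potential - vrev
  dG <- z * 96.485 * dv / 1000  # mV -> V
  direction <- if (abs(dv) < tol_mV) "equilibrium"
               else if (dG < 0) "influx" else "efflux"
  list(direction = direction, reversal_mV = vrev,
       delta_G_kJ_per_cycle_mol = dG)
}

#' Design a potassium diffusion-potential buffer
#'
#' For a valinomycin-mediated K+ diffusion potential, the required external
#' K+ is `k_in * 10^(target / slope)`. The added KCl is that requirement
#' minus the K+ already carried over from the diluted internal buffer,
#' floored at zero (with a warning when the carryover alone exceeds the
#' requirement); choline chloride tops the mixture up to a constant total
#' added salt.
#'
#' @param target target potential, mV (inside minus outside).
#' @param k_in internal K+ concentration, mM (> 0).
#' @param slope Nernst slope, mV/decade.
#' @param carryover_k K+ contributed by proteoliposome dilution, mM.
#' @param total_salt total added salt budget (KCl + CholineCl + carryover),
#'   mM.
#' @param digits rounding of the reported recipe, decimal places in mM
#'   (default 1, i.e. 0.1 mM).
#' @return list of class `buffer_recipe`: `target_potential`, `k_in`,
#'   `required_k_out`, `kcl_added`, `choline_added`, `carryover_k`,
#'   `total_salt`.
#' @export
k_diffusion_recipe <- function(target, k_in = 50, slope = 60,
                               carryover_k = 0, total_salt = 37.5,
                               digits = 1) {
  if (k_in <= 0) stop("k_in must be positive")
  required <- k_in * 10^(target / slope)
  if (required > total_salt)
    stop(sprintf("required external K+ (%.2f mM) exceeds the %.2f mM salt budget",
                 required, total_salt))
  kcl <- required - carryover_k
  if (kcl < 0) {
    warning(sprintf("carryover K+ (%.2f mM) alone exceeds the %.2f mM requirement; KCl floored at 0",
                    carryover_k, required))
    kcl <- 0
  }
  choline <- total_salt - kcl - carryover_k
  structure(list(target_potential = target, k_in = k_in,
                 required_k_out = round(required, digits),
                 kcl_added = round(kcl, digits),
                 choline_added = round(choline, digits),
                 carryover_k = carryover_k, total_salt = total_salt),
            class = "buffer_recipe")
}

#' @export
print.buffer_recipe <- function(x, ...) {
  cat(sprintf("<buffer_recipe> target %.2f mV: %.1f mM KCl + %.1f mM CholineCl (carryover K+ %.1f mM)\n",
              x$target_potential, x$kcl_added, x$choline_added,
              x$carryover_k))
  invisible(x)
}

#' External carryover composition after diluting proteoliposomes
#'
#' Each internal solute contributes `concentration / dilution_factor` to the
#' external medium; e.g. 50 mM internal KCl diluted 20-fold carries over
#' 2.5 mM K+, and 10 uM internal substrate yields 0.5 uM outside (a 20-fold
#' outward gradient).
#'
#' @param internal named numeric vector of internal concentrations.
#' @param dilution_factor dilution factor (> 1).
#' @return named numeric vector of carryover concentrations.
#' @export
dilution_state <- function(internal, dilution_factor) {
  if (dilution_factor <= 1) stop("dilution_factor must exceed 1")
  internal / dilution_factor
}

#' Reversal potentials and buffer recipes for candidate stoichiometries
#'
#' Tabulates, for each candidate number of co-transported sodium ions, the
#' reversal potential of the cycle and the KCl / choline chloride recipe
#' that imposes it as a K+ diffusion potential.
#'
#' @param n_na integer vector of candidate stoichiometries.
#' @inheritParams na_asp_cycle
#' @inheritParams k_diffusion_recipe
#' @return data frame with columns `n_na`, `z_net`, `reversal_mV`,
#'   `kcl_added_mM`, `choline_added_mM`.
#' @export
stoichiometry_plan <- function(n_na = c(2, 3, 4), na_mM = 200, asp_in = 10,
                               asp_out = 0.5, slope = 60, k_in = 50,
                               carryover_k = 0, total_salt = 37.5) {
  rows <- lapply(n_na, function(n) {
    cyc <- na_asp_cycle(n, na_mM, asp_in, asp_out, slope)
    v <- reversal_potential(cyc)
    rec <- k_diffusion_recipe(v, k_in, slope, carryover_k, total_salt)
    data.frame(n_na = n, z_net = net_charge(cyc),
               reversal_mV = round(v, 2), kcl_added_mM = rec$kcl_added,
               choline_added_mM = rec$choline_added)
  })
  do.call(rbind, rows)
}
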
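#' Construct a microspecies protonation network
#'
#' A microspecies network lists every protonation state (microspecies) of a
#' molecule relative to a single neutral reference species, together with
#' cumulative formation constants and reactive-channel annotations. The
#' formation constant of species \eqn{\sigma} is parameterized as
#' \eqn{\log_{10}\beta_\sigma} with
#' \eqn{\beta_\sigma = [\sigma] / ([\mathrm{ref}]\,[\mathrm{H}^+]^{n_\sigma})},
#' where \eqn{n_\sigma} is the proton count relative to the reference
#' (negative for net-deprotonated species). The reference has
#' \eqn{n = 0}, \eqn{\log_{10}\beta = 0} and charge 0.
#'
#' Species flagged `reactive` are elimination channels: each must carry an
#' activation barrier (kcal mol\eqn{^{-1}}) and/or an intrinsic first-order
#' rate constant (s\eqn{^{-1}}). If only the barrier is given the rate is
#' filled in via [eyring_rate()] at the network temperature.
#'
#' @param species A data frame with columns `label`, `n_protons`, `charge`,
#'   `log_beta`, and optionally `reactive` (logical), `barrier_kcal_mol`,
#'   `rate_s`.
#' @param molecule Compound label, e.g. `"PAB-PhQ"`.
#' @param temperature Temperature in K (stored; used to convert barriers to
#'   rates; equilibrium constants are treated as fitted at this temperature
#'   and are not van 't Hoff-corrected).
#'
#' @return An object of class `microspecies_network`.
#' @seealso [build_default_network()], [mole_fractions()], [predict_k_obs()]
#' @export
microspecies_network <- function(species, molecule = "custom",
                                 temperature = body_temperature) {
  if (!is.data.frame(species)) {
    stop("species must be a data frame", call. = FALSE)
  }
  required <- c("label", "n_protons", "charge", "log_beta")
  missing_cols <- setdiff(required, names(species))
  if (length(missing_cols) > 0) {
    stop("species is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(species$reactive)) species$reactive <- FALSE
  if (is.null(species$barrier_kcal_mol)) species$barrier_kcal_mol <- NA_real_
  if (is.null(species$rate_s)) species$rate_s <- NA_real_
  species$label <- as.character(species$label)
  species$reactive <- as.logical(species$reactive)

  if (anyDuplicated(species$label)) {
    stop("duplicate species labels: ",
         paste(unique(species$label[duplicated(species$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive value (K)", call. = FALSE)
  }
  if (any(!is.finite(species$log_beta))) {
    stop("non-finite log_beta values are not allowed", call. = FALSE)
  }
  if (any(species$n_protons != round(species$n_protons))) {
    stop("n_protons must be integers", call. = FALSE)
  }
  is_ref <- species$n_protons == 0 & species$log_beta == 0 & species$charge == 0
  if (sum(is_ref) != 1L) {
    stop("network must contain exactly one neutral reference species ",
         "(n_protons = 0, log_beta = 0, charge = 0); found ", sum(is_ref),
         call. = FALSE)
  }

  # fill intrinsic rates for reactive channels from their barriers
  need_rate <- species$reactive & is.na(species$rate_s)
  species$rate_s[need_rate] <-
    eyring_rate(species$barrier_kcal_mol[need_rate], temperature)
  bad <- species$reactive &
    (is.na(species$rate_s) | !is.finite(species$rate_s) | species$rate_s <= 0)
  if (any(bad)) {
    stop("reactive species without a usable barrier or intrinsic rate: ",
         paste(species$label[bad], collapse = ", "), call. = FALSE)
  }

  structure(
    list(molecule = molecule, temperature = temperature,
         species = species, reference = species$label[is_ref]),
    class = "microspecies_network"
  )
}

#' @export
print.microspecies_network <- function(x, ...) {
  cat("Microspecies network:", x$molecule,
      sprintf("(%d species, %d reactive, T = %.2f K)\n",
              nrow(x$species), sum(x$species$reactive), x$temperature))
  df <- x$species
  df$rate_s <- signif(df$rate_s, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# Built-in parameterizations for the three characterized para-aminobenzyl
# ketols. Barriers (kcal/mol) are the reference quantum-mechanical values;
# log_beta defaults are placeholder equilibrium constants chosen to respect
# the reported constraints (aniline deprotonation pK >= 16, carbonyl
# protonation pK <= -2, tertiary alcohol pK_O- ~ 8-12) and to give observed
# rate magnitudes in the reported range. Users fitting real profiles should
# treat them as starting values, not measurements.
.default_params <- list(
  "PAB-PhQ" = list(
    barriers  = c("NH-" = 11.8, "OH+" = 6.5, "Zw1" = 0.1),
    log_betas = c("NH3+" = 3.2, "NH-" = -18.5, "OH+" = -10.3, "O-" = -8.0,
                  "Zw1" = -17.44, "Zw2" = -4.8, "di-cation" = -7.1,
                  "di-anion" = -26.5)
  ),
  "PAB-BL" = list(
    barriers  = c("NH-" = 13.5, "OH+" = 13.5, "Zw1" = 1.4),
    log_betas = c("NH3+" = 3.0, "NH-" = -19.0, "OH+" = -5.25, "O-" = -9.0,
                  "Zw1" = -18.5, "Zw2" = -6.0, "di-cation" = -2.25,
                  "di-anion" = -28.0)
  ),
  "PAB-DN" = list(
    barriers  = c("NH-" = 13.0, "OH+" = 14.1, "Zw1" = 1.6),
    log_betas = c("NH3+" = 3.0, "NH-" = -19.0, "OH+" = -4.63, "O-" = -9.0,
                  "Zw1" = -17.81, "Zw2" = -6.0, "di-cation" = -1.63,
                  "di-anion" = -28.0)
  )
)

# species topology implied by three sites: aniline N (amphoteric),
# carbonyl O (basic), tertiary alcohol O (acidic); truncated to nine states
.default_topology <- data.frame(
  label     = c("neutral", "NH3+", "NH-", "OH+", "O-", "Zw1", "Zw2",
                "di-cation", "di-anion"),
  n_protons = c(0L, 1L, -1L, 1L, -1L, 0L, 0L, 2L, -2L),
  charge    = c(0L, 1L, -1L, 1L, -1L, 0L, 0L, 2L, -2L),
  stringsAsFactors = FALSE
)

#' Build the default nine-species network for a para-aminobenzyl ketol
#'
#' Creates the nine-state protonation network used throughout the package:
#' the neutral reference; singly protonated aniline (`NH3+`) and carbonyl
#' (`OH+`); singly deprotonated aniline (`NH-`) and tertiary alcohol (`O-`);
#' two zwitterions (`Zw1` = `NH-`+`OH+`, the reactive one; `Zw2` =
#' `NH3+`+`O-`); a dication and a dianion. The `NH-`, `OH+` and `Zw1`
#' channels are flagged reactive and carry activation barriers.
#'
#' For `"PAB-PhQ"`, `"PAB-BL"` and `"PAB-DN"` both barriers and default
#' equilibrium constants are built in; a custom molecule requires the
#' `barriers` mapping (and `log_betas` for every non-reference species it
#' wants to override). The default `log_betas` are placeholders consistent
#' with the qualitative pKa constraints of the system, not fitted values.
#'
#' @param molecule `"PAB-PhQ"`, `"PAB-BL"`, `"PAB-DN"` or a custom label.
#' @param barriers Named numeric vector of activation free energies
#'   (kcal mol\eqn{^{-1}}) for the reactive labels `NH-`, `OH+`, `Zw1`.
#'   Overrides the built-in values; required for custom molecules.
#' @param log_betas Named numeric vector of \eqn{\log_{10}\beta} values for
#'   non-reference species; overrides the defaults.
#' @param temperature Temperature in K used to convert barriers to rates.
#'
#' @return A validated [microspecies_network()] with nine species, three
#'   of them reactive.
#' @examples
#' net <- build_default_network("PAB-PhQ")
#' mole_fractions(net, 7.4)
#' @export
build_default_network <- function(molecule = c("PAB-PhQ", "PAB-BL", "PAB-DN"),
                                  barriers = NULL, log_betas = NULL,
                                  temperature = body_temperature) {
  if (length(molecule) != 1L) molecule <- match.arg(molecule)
  known <- molecule %in% names(.default_params)
  if (!known && is.null(barriers)) {
    stop("unknown compound label '", molecule,
         "': provide barriers (and log_betas) explicitly", call. = FALSE)
  }
  base_barriers <- if (known) .default_params[[molecule]]$barriers else
    c("NH-" = NA_real_, "OH+" = NA_real_, "Zw1" = NA_real_)
  base_lb <- if (known) .default_params[[molecule]]$log_betas else
    .default_params[["PAB-PhQ"]]$log_betas
  if (!is.null(barriers)) {
    unknown <- setdiff(names(barriers), c("NH-", "OH+", "Zw1"))
    if (length(unknown) > 0) {
      stop("barriers given for non-reactive label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    base_barriers[names(barriers)] <- barriers
  }
  if (any(is.na(base_barriers))) {
    stop("missing barrier for reactive species: ",
         paste(names(base_barriers)[is.na(base_barriers)], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(log_betas)) {
    unknown <- setdiff(names(log_betas), .default_topology$label)
    if (length(unknown) > 0) {
      stop("log_betas given for unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if ("neutral" %in% names(log_betas) && log_betas[["neutral"]] != 0) {
      stop("the neutral reference must keep log_beta = 0", call. = FALSE)
    }
    base_lb[setdiff(names(log_betas), "neutral")] <-
      log_betas[setdiff(names(log_betas), "neutral")]
  }

  sp <- .default_topology
  sp$log_beta <- c(0, unname(base_lb[sp$label[-1]]))
  sp$reactive <- sp$label %in% c("NH-", "OH+", "Zw1")
  sp$barrier_kcal_mol <- NA_real_
  sp$barrier_kcal_mol[sp$reactive] <- unname(base_barriers[sp$label[sp$reactive]])
  microspecies_network(sp, molecule = molecule, temperature = temperature)
}

#' pH-dependent mole fractions of the microspecies
#'
#' Computes, under the rapid pre-equilibrium assumption, the equilibrium
#' mole fraction of every microspecies at the given pH:
#' \deqn{x_\sigma(\mathrm{pH}) = \frac{\beta_\sigma [\mathrm{H}^+]^{n_\sigma}}
#'   {\sum_\tau \beta_\tau [\mathrm{H}^+]^{n_\tau}}, \qquad
#'   [\mathrm{H}^+] = 10^{-\mathrm{pH}}.}
#' The partition function is evaluated in log space with the log-sum-exp
#' trick so that networks whose formation constants span tens of log units
#' (aniline deprotonation pK >= 16 against carbonyl protonation pK <= -2)
#' stay finite at any practical pH.
#'
#' @param network A [microspecies_network()].
#' @param ph pH value(s); finite, may be a vector.
#'
#' @return For a single pH, a named numeric vector of fractions summing to
#'   1; for several pH values, a matrix with one row per pH (rownames are
#'   the pH values) and one column per species.
#' @examples
#' net <- build_default_network("PAB-PhQ")
#' rowSums(mole_fractions(net, c(2, 5, 7.4, 10)))
#' @export
mole_fractions <- function(network, ph) {
  stopifnot(inherits(network, "microspecies_network"))
  if (!is.numeric(ph) || length(ph) == 0 || any(!is.finite(ph))) {
    stop("ph must be finite numeric value(s)", call. = FALSE)
  }
  sp <- network$species
  ln10 <- log(10)
  # log10 of beta_sigma * [H+]^n = log_beta - n * pH ; rows = pH, cols = species
  lg <- outer(-ph, sp$n_protons) + rep(sp$log_beta, each = length(ph))
  lg <- lg * ln10  # natural log
  m <- apply(lg, 1L, max)
  w <- exp(lg - m)
  frac <- w / rowSums(w)
  colnames(frac) <- sp$label
  if (length(ph) == 1L) {
    return(stats::setNames(as.numeric(frac[1L, ]), sp$label))
  }
  rownames(frac) <- ph
  frac
}
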
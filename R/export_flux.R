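#' Martin-curve model of particle-delivered DNA export flux
#'
#' Encodes the empirical power-law attenuation of sinking particle flux with
#' depth, F(z) = F_ref * (z / z_ref)^(-b), applied to DNA: `F_ref` is the DNA
#' export flux at the reference depth `z_ref` (conventionally the base of the
#' euphotic zone), and `b` is the dimensionless attenuation exponent. All
#' parameters are configuration, not claims: `F_ref` in particular must be
#' set by the user from site-specific export production and a DNA quota.
#'
#' @param F_ref DNA export flux at `z_ref`, ug DNA m^-2 d^-1 (>= 0).
#' @param z_ref reference depth, m (> 0). Default 175 (base of the euphotic
#'   zone at a subtropical-gyre site).
#' @param b attenuation exponent (finite). Default 0.86, a canonical
#'   open-ocean value.
#' @param notes free-text provenance notes for the parameter values.
#' @return An object of class `flux_model`.
#' @export
flux_model <- function(F_ref, z_ref = 175, b = 0.86, notes = NULL) {
  stop_if_not_scalar_number(F_ref, "F_ref")
  stop_if_not_scalar_number(z_ref, "z_ref")
  stop_if_not_scalar_number(b, "b")
  if (F_ref < 0) stop("F_ref must be >= 0", call. = FALSE)
  if (z_ref <= 0) stop("z_ref must be > 0", call. = FALSE)
  structure(list(F_ref = F_ref, z_ref = z_ref, b = b, notes = notes),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf(
    "flux_model: F(z) = %g * (z / %g)^(-%g) ug DNA m^-2 d^-1\n",
    x$F_ref, x$z_ref, x$b
  ))
  if (!is.null(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

#' Evaluate the Martin curve at depth
#'
#' F(z) = F_ref * (z / z_ref)^(-b). Defined for z at or below the reference
#' depth; strictly decreasing in z for b > 0, constant for b = 0.
#'
#' @param z depth(s) in metres, each >= `model$z_ref`.
#' @param model a [flux_model()].
#' @return Flux at each depth, ug DNA m^-2 d^-1.
#' @export
martin_flux <- function(z, model) {
  stopifnot(inherits(model, "flux_model"), is.numeric(z))
  if (any(z < model$z_ref)) {
    stop("martin_flux is undefined above the reference depth", call. = FALSE)
  }
  model$F_ref * (z / model$z_ref)^(-model$b)
}

#' Free-DNA standing-stock profile
#'
#' Observed free-DNA concentrations by depth, plus the thickness of the layer
#' over which arriving areal flux is converted to a volumetric supply.
#'
#' @param depth depths in metres.
#' @param stock free-DNA standing stock at each depth, ug L^-1 (>= 0).
#' @param layer_m remineralisation layer thickness, m (> 0). Default 100.
#' @return An object of class `stock_profile`.
#' @export
stock_profile <- function(depth, stock, layer_m = 100) {
  stopifnot(is.numeric(depth), is.numeric(stock),
            length(depth) == length(stock))
  if (any(stock < 0)) stop("stocks must be non-negative", call. = FALSE)
  stop_if_not_scalar_number(layer_m, "layer_m")
  if (layer_m <= 0) stop("layer_m must be > 0", call. = FALSE)
  structure(list(depth = depth, stock = stock, layer_m = layer_m),
            class = "stock_profile")
}

stock_at <- function(stocks, z) {
  i <- match(z, stocks$depth)
  if (is.na(i)) stop(sprintf("no stock recorded at %g m", z), call. = FALSE)
  stocks$stock[i]
}

#' Daily particle-delivered DNA supply as a percentage of standing stock
#'
#' Converts the areal Martin flux at depth `z` to a volumetric daily supply
#' and expresses it as a percentage of the free-DNA standing stock at that
#' depth. Unit bookkeeping: flux (ug m^-2 d^-1) divided by the layer
#' thickness (m) gives ug m^-3 d^-1; dividing by 1,000 L m^-3 gives
#' ug L^-1 d^-1, commensurate with the stock.
#'
#' Two conversions are available. `mode = "deposit"` (default) assumes all
#' flux arriving at `z` is remineralised within the layer, i.e. supply =
#' F(z) / layer. `mode = "divergence"` uses the flux actually lost across the
#' layer, supply = (F(z) - F(z + layer)) / layer.
#'
#' @param z depth in metres (>= `model$z_ref`); must have a recorded stock.
#' @param model a [flux_model()].
#' @param stocks a [stock_profile()] with a positive stock at `z`.
#' @param mode `"deposit"` or `"divergence"` (see Details).
#' @return Percentage of the standing stock supplied per day (% d^-1).
#' @export
flux_supply_ratio <- function(z, model, stocks, mode = c("deposit", "divergence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stocks, "stock_profile"))
  s <- stock_at(stocks, z)
  if (s <= 0) stop("standing stock at z must be > 0", call. = FALSE)
  supply_areal <- switch(mode,
    deposit = martin_flux(z, model),
    divergence = martin_flux(z, model) - martin_flux(z + stocks$layer_m, model)
  )
  supply_vol <- supply_areal / stocks$layer_m / 1000  # ug L^-1 d^-1
  100 * supply_vol / s
}

#' Sweep Martin-curve parameters and report supply-ratio bounds per depth
#'
#' Evaluates [flux_supply_ratio()] over a grid of (`F_ref`, `b`) values and
#' reports the min and max ratio at each depth, the usual way of turning
#' parameter uncertainty into a printed range.
#'
#' @param F_ref_range,b_range numeric vectors giving the range (or explicit
#'   grid values) of each parameter.
#' @param stocks a [stock_profile()].
#' @param depths depths (m) at which to evaluate; default all stock depths at
#'   or below `z_ref`.
#' @param z_ref reference depth passed to [flux_model()].
#' @param n_grid number of grid points per parameter when a 2-value range is
#'   given.
#' @param mode passed to [flux_supply_ratio()].
#' @return data.frame with columns `depth`, `ratio_min`, `ratio_max` (% d^-1).
#' @export
sweep_parameters <- function(F_ref_range, b_range, stocks, depths = NULL,
                             z_ref = 175, n_grid = 11L,
                             mode = c("deposit", "divergence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stocks, "stock_profile"))
  expand_range <- function(r) {
    if (length(r) == 2L && r[1] != r[2]) seq(r[1], r[2], length.out = n_grid)
    else unique(r)
  }
  Fs <- expand_range(F_ref_range)
  bs <- expand_range(b_range)
  if (is.null(depths)) depths <- stocks$depth[stocks$depth >= z_ref]
  rows <- lapply(depths, function(z) {
    vals <- vapply(Fs, function(f) {
      vapply(bs, function(b) {
        flux_supply_ratio(z, flux_model(f, z_ref, b), stocks, mode)
      }, numeric(1))
    }, numeric(length(bs)))
    data.frame(depth = z, ratio_min = min(vals), ratio_max = max(vals))
  })
  do.call(rbind, rows)
}
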
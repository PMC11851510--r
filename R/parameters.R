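# The 187-parameter inventory: grouped containers, default calibration
# bounds, and flatten/unflatten helpers. The flattened ordering is the
# canonical design-vector ordering used everywhere (sensitivity, calibration,
# parameter files).

#' Microbial groups
#'
#' The thirteen microbial groups: acidogenic degraders of sugars (Asu), amino
#' acids (Aaa), glycerol (Agly) and long-chain/other acids (Aoa); acetogenic
#' degraders of propionate (Apro), butyrate (Abu) and valerate (Ava);
#' acetoclastic (Mac) and hydrogenotrophic (Mhyd) methanogens; and sulfate
#' reducers (Ss generic, Spro on propionate, Sac on acetate, Shyd on H2).
#'
#' @return Character vector of length 13.
#' @export
microbial_groups <- function() {
  c("Asu", "Aaa", "Agly", "Aoa", "Apro", "Abu", "Ava",
    "Mac", "Mhyd", "Ss", "Spro", "Sac", "Shyd")
}

#' Names of the 16 Monod saturation constants
#' @return Character vector of length 16.
#' @export
monod_names <- function() {
  c("kM_su_Asu", "kM_aa_Aaa", "kM_gly_Agly", "kM_oa_Aoa",
    "kM_pro_Apro", "kM_bu_Abu", "kM_va_Ava",
    "kM_H2_Mhyd", "kM_ac_Mac",
    "kM_Sat_Ss", "kM_pro_Spro", "kM_Sat_Spro",
    "kM_ac_Sac", "kM_Sat_Sac", "kM_H2_Shyd", "kM_Sat_Shyd")
}

#' Names of the 26 inhibition constants
#'
#' One VFA inhibition of hydrolysis plus 25 growth inhibitions: H2 on the
#' acetogens and Agly/Aoa, H2S on acetogens, methanogens and sulfate
#' reducers, NH3 on Mac, and five heavy metals (Cu, Zn, Cr, Pb, Ni) on Abu
#' and Mac.
#'
#' @return Character vector of length 26.
#' @export
inhibition_names <- function() {
  c("Kinh_VFA",
    paste0("Kinh_H2_", c("Agly", "Aoa", "Apro", "Abu", "Ava")),
    paste0("Kinh_H2S_", c("Apro", "Abu", "Ava", "Mac", "Mhyd",
                          "Ss", "Spro", "Sac", "Shyd")),
    "Kinh_NH3_Mac",
    paste0("Kinh_", rep(c("Cu", "Zn", "Cr", "Pb", "Ni"), each = 2),
           "_", rep(c("Abu", "Mac"), 5)))
}

#' Default calibration bounds for all 187 model parameters
#'
#' One row per parameter with its group label, lower and upper bound, in the
#' canonical flattened ordering. These ranges are the package's default
#' design space for sensitivity screening and calibration; they are plain
#' data and fully overridable.
#'
#' @return data.frame with columns `name`, `group`, `lo`, `up` (187 rows).
#' @export
default_parameter_bounds <- function() {
  g <- microbial_groups()
  hyd <- c("ch", "pr", "li")
  gases <- c("CH4", "CO2", "H2", "H2S", "NH3")
  prec <- precipitate_species()$name

  row <- function(name, group, lo, up) {
    data.frame(name = name, group = group, lo = lo, up = up,
               stringsAsFactors = FALSE)
  }
  mu_lo <- c(rep(0.5, 4), rep(0.2, 3), 0.1, 0.1, rep(0.1, 4))
  mu_up <- c(rep(5.0, 4), rep(2.0, 3), 1.2, 1.0, rep(1.0, 4))
  km_lo <- c(rep(0.05, 7), 0.02, 0.05, 0.02, 0.05, 0.02, 0.05, 0.02, 0.02, 0.02)
  km_up <- c(rep(2.0, 7), 0.2, 2.0, 1.0, 2.0, 1.0, 2.0, 1.0, 0.2, 1.0)
  kin_nm <- inhibition_names()
  kin_lo <- c(2, rep(1e-3, 5), rep(5e-3, 9), 0.02,
              rep(c(Cu = 5e-3, Zn = 2e-2, Cr = 5e-3, Pb = 5e-3, Ni = 5e-3),
                  each = 2))
  kin_up <- c(20, rep(5e-2, 5), rep(0.2, 9), 0.5,
              rep(c(Cu = 0.2, Zn = 0.5, Cr = 0.3, Pb = 0.3, Ni = 0.2),
                  each = 2))

  out <- rbind(
    row(paste0("X_init_", g), "X_init", 1e-3, 1.0),
    row(paste0("cE0_", hyd), "cE0", 1e-3, 0.4),
    row(paste0("mu_max_", g), "mu_max_Topt", mu_lo, mu_up),
    row(paste0("b_dec_", g), "b_dec", 0.01, 0.2),
    row(paste0("pK_lo_", g), "pK_lo", 4.5, 6.8),
    row(paste0("pK_up_", g), "pK_up", 7.2, 9.5),
    row(paste0("alpha_", g), "alpha", 0.005, 0.08),
    row(paste0("T_opt_", g), "T_opt", 30, 40),
    row(paste0("T_max_", g), "T_max", 45, 70),
    row(paste0("k_hyd_", hyd), "k_hyd", 0.1, 5),
    row(paste0("K_ME0_", hyd), "K_ME0", 0.5, 30),
    row(monod_names(), "k_M", km_lo, km_up),
    row(kin_nm, "K_inh", kin_lo, kin_up),
    row(c("K_M_Nio", "K_M_Pio"), "K_M_nutrient", 0.005, 0.2),
    row(paste0("KLa_a_", gases), "KLa_a",
        c(0.01, 0.005, 0.002, 0.002, 0.0002), c(0.5, 0.1, 0.05, 0.02, 0.002)),
    row(paste0("KLa_b_", gases), "KLa_b",
        c(0.5, 0.2, 0.05, 0.05, 0.005), c(10, 3, 1, 0.8, 0.05)),
    row(paste0("k_cryst_", prec), "k_cryst", 0.5, 20)
  )
  rownames(out) <- NULL
  stopifnot(nrow(out) == 187L, all(out$lo < out$up))
  out
}

.param_group_sizes <- c(
  X_init = 13L, cE0 = 3L, mu_max_Topt = 13L, b_dec = 13L, pK_lo = 13L,
  pK_up = 13L, alpha = 13L, T_opt = 13L, T_max = 13L, k_hyd = 3L,
  K_ME0 = 3L, k_M = 16L, K_inh = 26L, K_M_nutrient = 2L,
  KLa_a = 5L, KLa_b = 5L, k_cryst = 20L
)

#' Build a ModelParameters object from a flattened vector
#'
#' @param x Numeric vector of length 187 in the canonical ordering of
#'   [default_parameter_bounds()].
#' @param bounds Optional bounds table used for validation.
#' @param validate Check bounds and ordering invariants (default TRUE).
#' @return An object of class `ad_parameters`: a list of grouped named
#'   vectors.
#' @export
params_from_vector <- function(x, bounds = default_parameter_bounds(),
                               validate = TRUE) {
  if (length(x) != 187L) {
    stop("parameter vector must have exactly 187 entries, got ", length(x))
  }
  g <- microbial_groups()
  hyd <- c("ch", "pr", "li")
  gases <- c("CH4", "CO2", "H2", "H2S", "NH3")
  prec <- precipitate_species()$name
  sizes <- .param_group_sizes
  idx <- cumsum(sizes)
  take <- function(grp) {
    i <- match(grp, names(sizes))
    x[(idx[i] - sizes[i] + 1L):idx[i]]
  }
  p <- list(
    X_init = stats::setNames(take("X_init"), g),
    cE0 = stats::setNames(take("cE0"), hyd),
    mu_max_Topt = stats::setNames(take("mu_max_Topt"), g),
    b_dec = stats::setNames(take("b_dec"), g),
    pK_lo = stats::setNames(take("pK_lo"), g),
    pK_up = stats::setNames(take("pK_up"), g),
    alpha = stats::setNames(take("alpha"), g),
    T_opt = stats::setNames(take("T_opt"), g),
    T_max = stats::setNames(take("T_max"), g),
    k_hyd = stats::setNames(take("k_hyd"), hyd),
    K_ME0 = stats::setNames(take("K_ME0"), hyd),
    k_M = stats::setNames(take("k_M"), monod_names()),
    K_inh = stats::setNames(take("K_inh"), inhibition_names()),
    K_M_nutrient = stats::setNames(take("K_M_nutrient"),
                                   c("K_M_Nio", "K_M_Pio")),
    KLa_a = stats::setNames(take("KLa_a"), gases),
    KLa_b = stats::setNames(take("KLa_b"), gases),
    k_cryst = stats::setNames(take("k_cryst"), prec)
  )
  class(p) <- "ad_parameters"
  if (validate) validate_parameters(p, bounds)
  p
}

#' Flatten a ModelParameters object to the canonical 187-vector
#' @param p An `ad_parameters` object.
#' @return Named numeric vector of length 187.
#' @export
params_to_vector <- function(p) {
  stopifnot(inherits(p, "ad_parameters"))
  v <- unlist(p[names(.param_group_sizes)], use.names = FALSE)
  stats::setNames(v, default_parameter_bounds()$name)
}

#' Validate a ModelParameters object
#'
#' Checks group sizes (flattened length exactly 187), positivity, bound
#' membership, and the ordering constraints pK_lo < pK_up and T_opt < T_max.
#'
#' @param p An `ad_parameters` object.
#' @param bounds Bounds table; set to NULL to skip the bound check.
#' @param tol Relative slack allowed outside the bounds.
#' @return Invisibly TRUE; stops with a message naming the offender.
#' @export
validate_parameters <- function(p, bounds = default_parameter_bounds(),
                                tol = 1e-9) {
  sz <- vapply(p[names(.param_group_sizes)], length, integer(1))
  bad <- which(sz != .param_group_sizes)
  if (length(bad)) {
    stop("parameter group ", names(sz)[bad[1]], " has length ", sz[bad[1]],
         ", expected ", .param_group_sizes[bad[1]])
  }
  v <- params_to_vector(p)
  if (any(!is.finite(v))) stop("non-finite parameter: ", names(v)[which(!is.finite(v))[1]])
  if (any(v < 0)) stop("negative parameter: ", names(v)[which(v < 0)[1]])
  if (any(p$pK_lo >= p$pK_up)) {
    stop("pK_lo >= pK_up for group ", names(which(p$pK_lo >= p$pK_up))[1])
  }
  if (any(p$T_opt >= p$T_max)) {
    stop("T_opt >= T_max for group ", names(which(p$T_opt >= p$T_max))[1])
  }
  if (!is.null(bounds)) {
    slack <- tol * pmax(1, abs(bounds$up))
    out_lo <- v < bounds$lo - slack
    out_up <- v > bounds$up + slack
    if (any(out_lo | out_up)) {
      i <- which(out_lo | out_up)[1]
      stop("parameter ", bounds$name[i], " = ", v[i], " outside [",
           bounds$lo[i], ", ", bounds$up[i], "]")
    }
  }
  invisible(TRUE)
}

#' Midpoint parameter set
#'
#' The initial design of the calibration procedure: every parameter at the
#' midpoint of its bound interval.
#'
#' @param bounds Bounds table.
#' @return An `ad_parameters` object.
#' @export
midpoint_parameters <- function(bounds = default_parameter_bounds()) {
  params_from_vector((bounds$lo + bounds$up) / 2, bounds)
}

#' @export
print.ad_parameters <- function(x, ...) {
  cat("<ad_parameters> 187 calibratable constants in",
      length(.param_group_sizes), "groups\n")
  for (nm in names(.param_group_sizes)) {
    v <- x[[nm]]
    cat(sprintf("  %-13s [%d]  %.4g .. %.4g\n", nm, length(v),
                min(v), max(v)))
  }
  invisible(x)
}

#' Write / read a full parameter set as YAML
#'
#' The file stores all 187 named entries; reading a file with any entry
#' missing is a hard error listing the missing names.
#'
#' @param p An `ad_parameters` object.
#' @param path File path.
#' @return `read_parameters` returns an `ad_parameters` object.
#' @export
write_parameters <- function(p, path) {
  v <- params_to_vector(p)
  txt <- yaml::as.yaml(as.list(v), precision = 17L)
  atomic_write(txt, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  want <- default_parameter_bounds()$name
  missing <- setdiff(want, names(raw))
  if (length(missing)) {
    stop("parameter file ", path, " is missing ", length(missing),
         " entries: ", paste(missing, collapse = ", "))
  }
  params_from_vector(as.numeric(raw[want]))
}

#' Bounds centred on a parameter set
#'
#' Builds a calibration design space as a symmetric relative interval around
#' a reference parameter set (clipped to positive values). Useful for local
#' calibration studies where the screening step should reflect sensitivity
#' near the reference rather than across the full literature ranges.
#'
#' @param params Reference `ad_parameters`.
#' @param spread Half-width as a fraction of the reference value.
#' @return A bounds data.frame like [default_parameter_bounds()].
#' @export
bounds_around <- function(params, spread = 0.3) {
  stopifnot(spread > 0, spread < 1)
  v <- params_to_vector(params)
  b <- default_parameter_bounds()
  b$lo <- v * (1 - spread)
  b$up <- v * (1 + spread)
  b
}
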
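# Shared toy setups. Everything is generated in code; the "toy" study uses
# the B1 reactor over a short horizon with the coarse Euler grid so embedded
# simulations stay cheap.

toy_dt <- 0.025

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_reactor <- function(t_total = 12) b1_bioreactor(t_total)

toy_sim <- function(params = midpoint_parameters(), t_total = 12,
                    method = "euler", dt = toy_dt, ...) {
  simulate_ad(params, toy_reactor(t_total), b1_feedstock(), dt = dt,
              method = method, ...)
}

# parameters for a single-group (Asu) reduction with chemistry, gas
# transfer and all other groups switched off; validate = FALSE because the
# switched-off values sit outside the calibration bounds on purpose
one_group_params <- function() {
  p <- midpoint_parameters()
  v <- params_to_vector(p)
  v[grep("^X_init_", names(v))] <- 0
  v["X_init_Asu"] <- 0.1
  v[c("cE0_pr", "cE0_li")] <- 0
  v["cE0_ch"] <- 0.1
  v[grep("^KLa_", names(v))] <- 0
  v[grep("^k_cryst_", names(v))] <- 0
  v["pK_lo_Asu"] <- 1
  v["pK_up_Asu"] <- 13
  params_from_vector(v, validate = FALSE)
}

# a state vector with hand-set entries on top of zeros
state_with <- function(...) {
  s <- stats::setNames(numeric(80), state_names())
  vals <- c(...)
  s[names(vals)] <- vals
  s
}
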
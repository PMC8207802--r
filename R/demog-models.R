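# The four two-population demographic models fitted to the joint SFS.
#
# All sizes are diploid sizes relative to the ancestral size Nanc, times
# are in units of 2*Nanc generations, and migration rates are scaled as
# 2*Nanc*m (m = per-generation migrant fraction; m12 = into population 1
# from population 2).
#
#   A  split, constant sizes, no gene flow:        nu1, nu2, T
#   B  split, constant sizes, asymmetric flow:     nu1, nu2, T, m12, m21
#   C  split, sizes change linearly from nu1/nu2   nu1, nu2, nu1F, nu2F,
#      to nu1F/nu2F over the whole epoch, flow:    T, m12, m21
#   D  as C but with a constant epoch first: the   nu1, nu2, nu1F, nu2F,
#      linear change occupies the final fraction   T, rT2, m12, m21
#      rT2 of the split epoch
#
# A is nested in B (m -> 0) and B in C (nuF -> nu); D adds one epoch
# boundary to C.  Linear (rather than exponential) size trajectories are
# used so the fitted geometry matches the trapezoid-shaped population
# histories the simulator generates.

#' Catalogue of demographic models
#'
#' @param model optional model id ("A", "B", "C", "D"); if missing, the
#'   whole catalogue is returned.
#' @return a model spec (list with `id`, `par_names`, `k`, `lower`,
#'   `upper`, `logit` flags) or a named list of all four.
#' @export
demographic_models <- function(model) {
  base <- function(id, par_names, logit) {
    lower <- ifelse(logit, 0.02,
                    ifelse(par_names %in% c("m12", "m21"), 1e-4,
                           ifelse(par_names == "T", 1e-4, 1e-3)))
    upper <- ifelse(logit, 0.98,
                    ifelse(par_names %in% c("m12", "m21"), 20,
                           ifelse(par_names == "T", 5, 100)))
    list(id = id, par_names = par_names, k = length(par_names),
         lower = lower, upper = upper, logit = logit)
  }
  cat <- list(
    A = base("A", c("nu1", "nu2", "T"), c(FALSE, FALSE, FALSE)),
    B = base("B", c("nu1", "nu2", "T", "m12", "m21"), rep(FALSE, 5)),
    C = base("C", c("nu1", "nu2", "nu1F", "nu2F", "T", "m12", "m21"),
             rep(FALSE, 7)),
    D = base("D", c("nu1", "nu2", "nu1F", "nu2F", "T", "rT2", "m12", "m21"),
             c(rep(FALSE, 5), TRUE, FALSE, FALSE))
  )
  if (missing(model)) return(cat)
  m <- toupper(model)
  if (!m %in% names(cat)) stop("unknown demographic model: ", model)
  cat[[m]]
}

check_params <- function(spec, params) {
  if (length(params) != spec$k)
    stop(sprintf("model %s expects %d parameters (%s)", spec$id, spec$k,
                 paste(spec$par_names, collapse = ", ")))
  p <- setNames(as.numeric(params), spec$par_names)
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p[grep("^nu", names(p))] <= 0)) stop("population sizes must be > 0")
  if (p["T"] < 0) stop("split time must be >= 0")
  if (any(p[names(p) %in% c("m12", "m21")] < 0)) stop("migration must be >= 0")
  invisible(p)
}

# nu trajectories (forward time tau in [0, T] since the split)
model_nu_fun <- function(spec, p) {
  p <- setNames(as.numeric(p), spec$par_names)
  Tt <- p["T"]
  switch(spec$id,
    A = ,
    B = list(nu1 = function(t) rep(p["nu1"], length(t)),
             nu2 = function(t) rep(p["nu2"], length(t)),
             m12 = if (spec$id == "A") 0 else p["m12"],
             m21 = if (spec$id == "A") 0 else p["m21"],
             T = Tt),
    C = list(nu1 = function(t) p["nu1"] + (p["nu1F"] - p["nu1"]) * t / Tt,
             nu2 = function(t) p["nu2"] + (p["nu2F"] - p["nu2"]) * t / Tt,
             m12 = p["m12"], m21 = p["m21"], T = Tt),
    D = {
      T2 <- p["rT2"] * Tt
      Tc <- Tt - T2
      list(
        nu1 = function(t) ifelse(t <= Tc, p["nu1"],
                p["nu1"] + (p["nu1F"] - p["nu1"]) * (t - Tc) / T2),
        nu2 = function(t) ifelse(t <= Tc, p["nu2"],
                p["nu2"] + (p["nu2F"] - p["nu2"]) * (t - Tc) / T2),
        m12 = p["m12"], m21 = p["m21"], T = Tt)
    })
}

# discretised trajectory for the integrators: per-step dt and midpoint nus
model_trajectory <- function(spec, params, dt_max = 1e-3, min_steps = 20L,
                             max_steps = 2000L) {
  fun <- model_nu_fun(spec, params)
  Tt <- fun$T
  if (Tt <= 0)
    return(list(dts = numeric(0), nu1 = numeric(0), nu2 = numeric(0),
                m12 = fun$m12, m21 = fun$m21))
  nstep <- min(max(as.integer(min_steps), ceiling(Tt / dt_max)),
               as.integer(max_steps))
  dt <- Tt / nstep
  mid <- (seq_len(nstep) - 0.5) * dt
  list(dts = rep(dt, nstep), nu1 = pmax(fun$nu1(mid), 1e-6),
       nu2 = pmax(fun$nu2(mid), 1e-6), m12 = fun$m12, m21 = fun$m21)
}
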
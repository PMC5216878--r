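# Demographic models of the Mesoamerican/Andean domestication history and
# parameter priors for the coalescent null.
#
# Two four-population scenarios are supported. Both derive the Andean (AW)
# and Mesoamerican (MW) wild pools from one ancestral pool, with an
# independent domestication bottleneck in each pool (MD, AD). Model 1 places
# the Andean founder bottleneck recently and keeps wild sizes constant;
# Model 2 puts that bottleneck immediately after the split from the
# Mesoamerican pool and lets the wild pools grow exponentially toward the
# present (implemented as a log-linear piecewise-constant staircase).
#
# Sizes are haploid effective sizes, times in generations (generation time
# one year for an annual crop), migration rates are per-lineage backward
# rates per generation. Bottleneck intensity I is the bottleneck size as a
# percentage of the pre-bottleneck (ancestral wild) size, applied between
# the end and beginning times of the corresponding domestication window.

#' Default demographic parameters
#'
#' Reconstruction at literature scale for the common-bean history (the
#' original prior table is not public); see the package vignette for the
#' reasoning behind each value.
#'
#' @return named list of parameters using the standard symbol names
#'   (`T_ANC, T_BAB, T_EAB, T_BMD, T_BAD, T_EMD, T_EAD, N_ANC, N_BA,
#'   N_MWANC, N_AWANC, N_MD, N_MW, N_AW, N_AD, I_MD, I_AD, M_WD, M_DW,
#'   M_MWAW, M_AWMW`).
#' @export
default_demography_params <- function() {
  list(T_ANC = 150000, T_BAB = 30000, T_EAB = 28000,
       T_BMD = 8000, T_EMD = 6000, T_BAD = 8000, T_EAD = 6000,
       N_ANC = 250000, N_BA = 6000, N_MWANC = 250000, N_AWANC = 120000,
       N_MD = 250000, N_MW = 250000, N_AW = 120000, N_AD = 60000,
       I_MD = 0.2, I_AD = 0.5,
       M_WD = 5e-5, M_DW = 1e-5, M_MWAW = 0, M_AWMW = 0)
}

validate_demography_params <- function(p) {
  need <- names(default_demography_params())
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  times <- c("T_ANC", "T_BAB", "T_EAB", "T_BMD", "T_BAD", "T_EMD", "T_EAD")
  sizes <- c("N_ANC", "N_BA", "N_MWANC", "N_AWANC", "N_MD", "N_MW", "N_AW", "N_AD")
  if (any(unlist(p[times]) < 0)) return("negative time")
  if (any(unlist(p[sizes]) <= 0)) return("non-positive size")
  if (p$I_MD <= 0 || p$I_MD > 100 || p$I_AD <= 0 || p$I_AD > 100)
    return("bottleneck intensity outside (0, 100]")
  if (any(unlist(p[c("M_WD", "M_DW", "M_MWAW", "M_AWMW")]) < 0))
    return("negative migration rate")
  if (p$T_EMD >= p$T_BMD) return("T_EMD must precede T_BMD")
  if (p$T_EAD >= p$T_BAD) return("T_EAD must precede T_BAD")
  if (p$T_EAB >= p$T_BAB) return("T_EAB must precede T_BAB")
  if (p$T_BMD > p$T_ANC || p$T_BAD > p$T_ANC || p$T_BAB > p$T_ANC)
    return("domestication/founder events must predate the pool split")
  NULL
}

#' Construct a demographic model
#'
#' @param model_id 1 (recent Andean founder bottleneck, constant wild
#'   sizes) or 2 (founder bottleneck just after the split, exponentially
#'   growing wild pools).
#' @param params parameter list as from [default_demography_params()];
#'   values given override the defaults. For Model 2 the Andean founder
#'   bottleneck is pinned to the split (`T_BAB = T_ANC`).
#' @param growth_steps staircase resolution for Model 2's exponential wild
#'   growth.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(model_id = 1L, params = list(), growth_steps = 12L) {
  stopifnot(model_id %in% c(1L, 2L))
  p <- utils::modifyList(default_demography_params(), params)
  if (model_id == 2L && !("T_BAB" %in% names(params))) {
    p$T_BAB <- p$T_ANC
    p$T_EAB <- min(p$T_EAB, p$T_BAB - 1)
  }
  err <- validate_demography_params(p)
  if (!is.null(err)) stop("invalid demographic parameters: ", err)
  structure(list(model_id = as.integer(model_id), params = p,
                 growth_steps = as.integer(growth_steps)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> Model %d; T_BMD=%g T_EMD=%g I_MD=%g%% N_MW=%g\n",
              x$model_id, x$params$T_BMD, x$params$T_EMD, x$params$I_MD,
              x$params$N_MW))
  invisible(x)
}

# staircase breakpoints for log-linear size change on (0, t_end)
.growth_breaks <- function(n_from, n_to, t_end, steps) {
  ts <- seq(0, t_end, length.out = steps + 1L)
  mids <- exp(log(n_from) + (log(n_to) - log(n_from)) *
                ((head(ts, -1L) + ts[-1L]) / 2) / t_end)
  list(t = head(ts, -1L), size = mids)
}

# Compile a model into piecewise-constant epochs for the coalescent engine.
# populations: subset of c("MW","MD","AW","AD") present in the sample; the
# returned deme indices follow that order (0-based for C++).
#' @keywords internal
build_epochs <- function(model, populations = c("MW", "MD")) {
  p <- model$params
  pops <- c("MW", "MD", "AW", "AD")
  stopifnot(all(populations %in% pops))
  use4 <- any(c("AW", "AD") %in% populations)
  demes <- if (use4) pops else c("MW", "MD")
  nd <- length(demes)
  di <- setNames(seq_len(nd), demes)

  # deme size as a function of epoch start time
  size_at <- function(deme, t) {
    switch(deme,
      MW = if (t >= p$T_ANC) p$N_ANC else if (t >= p$T_BMD) p$N_MWANC
           else if (model$model_id == 2L)
             exp(log(p$N_MW) + (log(p$N_MWANC) - log(p$N_MW)) * t / p$T_BMD)
           else p$N_MW,
      MD = if (t >= p$T_EMD) p$I_MD / 100 * p$N_MWANC else p$N_MD,
      AW = if (t >= p$T_BAB) p$N_AWANC
           else if (t >= p$T_EAB) p$N_BA
           else if (model$model_id == 2L)
             exp(log(p$N_AW) + (log(p$N_AWANC) - log(p$N_AW)) * t / p$T_EAB)
           else p$N_AW,
      AD = if (t >= p$T_EAD) p$I_AD / 100 * p$N_AWANC else p$N_AD)
  }

  breaks <- c(0, p$T_EMD, p$T_BMD)
  if (use4) breaks <- c(breaks, p$T_EAD, p$T_BAD, p$T_EAB, p$T_BAB, p$T_ANC)
  if (model$model_id == 2L) {
    gs <- .growth_breaks(p$N_MW, p$N_MWANC, p$T_BMD, model$growth_steps)
    breaks <- c(breaks, gs$t)
    if (use4) {
      ga <- .growth_breaks(p$N_AW, p$N_AWANC, p$T_EAB, model$growth_steps)
      breaks <- c(breaks, ga$t)
    }
  }
  breaks <- sort(unique(breaks))
  merged_md <- function(t) t >= p$T_BMD
  merged_ad <- function(t) use4 && t >= p$T_BAD
  merged_aw <- function(t) use4 && t >= p$T_ANC

  epochs <- lapply(breaks, function(t0) {
    sizes <- vapply(demes, size_at, 0, t = t0)
    mig <- matrix(0, nd, nd)
    if (!merged_md(t0)) {             # MD and MW both alive
      mig[di["MD"], di["MW"]] <- p$M_WD   # forward wild->dom gene flow
      mig[di["MW"], di["MD"]] <- p$M_DW
    }
    if (use4 && !merged_aw(t0)) {     # AW and MW both alive
      mig[di["AW"], di["MW"]] <- p$M_MWAW
      mig[di["MW"], di["AW"]] <- p$M_AWMW
    }
    moves <- NULL
    mv <- list()
    if (t0 == p$T_BMD) mv[[length(mv) + 1L]] <- c(di["MD"], di["MW"])
    if (use4 && t0 == p$T_BAD) mv[[length(mv) + 1L]] <- c(di["AD"], di["AW"])
    if (use4 && t0 == p$T_ANC) mv[[length(mv) + 1L]] <- c(di["AW"], di["MW"])
    if (length(mv)) moves <- do.call(rbind, mv) - 1L  # 0-based for C++
    list(t_start = t0, sizes = unname(sizes), mig = mig, moves = moves)
  })
  list(epochs = epochs, demes = demes)
}

# ---- priors ---------------------------------------------------------------

#' Prior specifications for model parameters
#'
#' A prior set is a named list mapping parameter names to distribution
#' specs: `list(dist = "fixed", value =)`, `list(dist = "unif", min =,
#' max =)`, `list(dist = "logunif", min =, max =)` or `list(dist =
#' "lognorm", mean =, sdlog =)` (parameterized by the arithmetic mean).
#' Parameters without a spec stay at their base values. Draws violating the
#' model invariants are rejected and redrawn.
#'
#' `fixed_priors()` pins every parameter at the supplied truth (the mode
#' used when testing the scan against a generator with known parameters);
#' `default_priors()` loads the shipped wide reconstruction
#' (`extdata/demography_priors.json`), clearly labeled as such.
#'
#' @param params parameter list to pin.
#' @return a prior set (named list).
#' @export
fixed_priors <- function(params = default_demography_params()) {
  lapply(params, function(v) list(dist = "fixed", value = v))
}

#' @rdname fixed_priors
#' @param model_id which model's prior block to load.
#' @export
default_priors <- function(model_id = 1L) {
  path <- system.file("extdata", "demography_priors.json", package = "beanscan")
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg[[paste0("model", model_id)]]
}

.draw_prior <- function(spec) {
  switch(spec$dist,
         fixed = spec$value,
         unif = runif(1L, spec$min, spec$max),
         logunif = exp(runif(1L, log(spec$min), log(spec$max))),
         lognorm = {
           sdl <- spec$sdlog
           rlnorm_mean <- log(spec$mean) - sdl^2 / 2
           exp(rnorm(1L, rlnorm_mean, sdl))
         },
         stop("unknown prior distribution: ", spec$dist))
}

#' Sample a parameter set from priors
#'
#' @param priors a prior set (see [fixed_priors()]).
#' @param base base parameter list for parameters without a prior.
#' @param max_reject rejection budget for invariant-violating draws.
#' @return list with `params` and `n_rejected`.
#' @export
sample_model_params <- function(priors, base = default_demography_params(),
                                max_reject = 1000L) {
  for (r in seq_len(max_reject)) {
    p <- base
    for (nm in names(priors)) p[[nm]] <- .draw_prior(priors[[nm]])
    if (is.null(validate_demography_params(p)))
      return(list(params = p, n_rejected = r - 1L))
  }
  stop("could not draw valid demographic parameters from the priors")
}

#' Mutation-rate priors per fragment class
#'
#' Mean 1e-8 per site per generation for intronic (noncoding) fragments and
#' a 10-fold lower mean for exonic fragments; `sdlog = 0` pins the rates at
#' their means.
#'
#' @param mean_intron,mean_exon prior means.
#' @param sdlog lognormal spread (0 = fixed).
#' @return list with one spec per class (`exonic`, `intronic`).
#' @export
mutation_rate_priors <- function(mean_intron = 1e-8, mean_exon = 1e-9,
                                 sdlog = 0) {
  mk <- function(mu) if (sdlog == 0) list(dist = "fixed", value = mu)
                     else list(dist = "lognorm", mean = mu, sdlog = sdlog)
  list(exonic = mk(mean_exon), intronic = mk(mean_intron))
}

#' Read or write a demography configuration (JSON)
#'
#' The file carries `model_id`, a `params` block with the standard symbol
#' names, and optionally a `priors` block.
#'
#' @param path JSON file.
#' @export
read_demography_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- demographic_model(cfg$model_id %||% 1L,
                             lapply(cfg$params %||% list(), unlist))
  list(model = model, priors = cfg$priors)
}

#' @rdname read_demography_config
#' @param model a [demographic_model()].
#' @param priors optional prior set.
#' @export
write_demography_config <- function(model, path, priors = NULL) {
  jsonlite::write_json(list(model_id = model$model_id, params = model$params,
                            priors = priors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
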
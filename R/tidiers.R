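# broom-style tidiers for the package's fitted objects.

#' Tidy an equilibrium relation
#'
#' @param x An [fit_equilibrium_relation()] object.
#' @param ... Unused.
#' @return A tibble: `isotope`, `intercept`, `slope`, `r`.
#' @method tidy equilibrium_relation
#' @export
tidy.equilibrium_relation <- function(x, ...) {
  tibble(
    isotope = c("2H", "18O"),
    intercept = c(x$d$coef[["intercept"]], x$o$coef[["intercept"]]),
    slope = c(x$d$coef[["slope"]], x$o$coef[["slope"]]),
    r = c(x$d$r, x$o$r)
  )
}

#' @rdname tidy.equilibrium_relation
#' @method glance equilibrium_relation
#' @export
glance.equilibrium_relation <- function(x, ...) {
  tibble(n = x$n, r_d = x$d$r, r_o = x$o$r, valid = x$valid)
}

#' Tidy a candidate DEE model fit
#'
#' @param x A [fit_dee_model()] object.
#' @param ... Unused.
#' @return Coefficient table: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy dee_model_fit
#' @export
tidy.dee_model_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @rdname tidy.dee_model_fit
#' @method glance dee_model_fit
#' @export
glance.dee_model_fit <- function(x, ...) {
  tibble(design = x$design, kind = x$kind, n = x$n, k = x$k,
         logLik = x$logLik, aicc = x$aicc, r = x$r)
}

#' Tidy an HMM fit
#'
#' One row per stream, state and parameter, plus the implied emission mean
#' per stream and state.
#'
#' @param x An [hmm_fit()] object.
#' @param ... Unused.
#' @return A tibble: `stream`, `state`, `parameter`, `value`.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  sp <- x$spec
  purrr::map_dfr(names(sp$emissions), function(nm) {
    em <- sp$emissions[[nm]]
    purrr::map_dfr(seq_along(sp$states), function(s) {
      p <- em$pars[[s]]
      tibble(stream = nm, state = sp$states[s],
             parameter = c(names(p), "mean"),
             value = c(unlist(p), em_mean(em$family, p)))
    })
  })
}

#' @rdname tidy.hmm_fit
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_minutes = x$n_minutes)
}
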
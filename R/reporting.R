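# Scenario configs and table export.
#
# A scenario is a plain list (or a JSON file holding one) with blocks:
#   test:       theta0, alpha, sigma2
#   priors:     list of prior specs:
#                 {type: "point"|"normal"|"skew_normal"|"trunc_normal"|"mixture",
#                  theta_d, n_d, lambda, lower, upper, w0,
#                  components: [{theta_d, n_d}, {theta_d, n_d}],
#                  variance_prior: {shape, scale}, label}
#   evaluation: n (vector), method ("quadrature"|"mc"), M, seed
#   ssd:        fraction (or thresholds per measure), measures, n_max, method
# Config errors carry the offending field path and condition class
# "posdesign_config_error" so the CLI can map them to exit code 2.

.cfg_fail <- function(path, msg) {
  stop(structure(class = c("posdesign_config_error", "error", "condition"),
                 list(message = sprintf("config error at '%s': %s", path, msg),
                      call = NULL)))
}

.cfg_num <- function(x, path, default = NULL) {
  if (is.null(x)) {
    if (!is.null(default)) return(default)
    .cfg_fail(path, "missing required numeric field")
  }
  if (!is.numeric(x)) .cfg_fail(path, "must be numeric")
  x
}

#' Read and validate a scenario configuration
#'
#' @param x a list, or the path of a JSON file containing one.
#' @return the validated config list, with defaults filled in, ready for
#'   [run_compute()], [run_ssd()] and [run_curves()].
#' @export
read_scenario <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) .cfg_fail(x, "file not found")
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  if (!is.list(x)) .cfg_fail("<root>", "config must be a list")
  tb <- x$test
  x$test <- list(theta0 = .cfg_num(tb$theta0, "test.theta0", 0),
                 alpha = .cfg_num(tb$alpha, "test.alpha", 0.05),
                 sigma2 = .cfg_num(tb$sigma2, "test.sigma2", 4))
  if (x$test$sigma2 <= 0) .cfg_fail("test.sigma2", "must be positive")
  if (is.null(x$priors) || !length(x$priors))
    .cfg_fail("priors", "at least one prior spec is required")
  ev <- x$evaluation
  x$evaluation <- list(
    n = as.numeric(unlist(if (is.null(ev$n)) c(100, 500) else ev$n)),
    method = if (is.null(ev$method)) "quadrature" else ev$method,
    M = .cfg_num(ev$M, "evaluation.M", 1e6),
    seed = if (is.null(ev$seed)) NULL else .cfg_num(ev$seed, "evaluation.seed"))
  if (!x$evaluation$method %in% c("quadrature", "mc"))
    .cfg_fail("evaluation.method", "must be \"quadrature\" or \"mc\"")
  sb <- x$ssd
  x$ssd <- list(fraction = .cfg_num(sb$fraction, "ssd.fraction", 0.8),
                measures = if (is.null(sb$measures)) c("u", "a", "b", "c")
                           else unlist(sb$measures),
                n_max = .cfg_num(sb$n_max, "ssd.n_max", 1e6),
                method = if (is.null(sb$method)) "quadrature" else sb$method)
  if (!all(x$ssd$measures %in% c("u", "a", "b", "c")))
    .cfg_fail("ssd.measures", "measures must be among u, a, b, c")
  # build priors eagerly so malformed specs fail at read time
  for (i in seq_along(x$priors))
    .build_prior(x$priors[[i]], sqrt(x$test$sigma2),
                 sprintf("priors[%d]", i))
  x
}

.build_prior <- function(spec, sigma, path = "prior") {
  if (is.null(spec$type)) .cfg_fail(paste0(path, ".type"), "missing type")
  pri <- switch(spec$type,
    point = point_prior(.cfg_num(spec$theta_d, paste0(path, ".theta_d"))),
    normal = normal_prior(.cfg_num(spec$theta_d, paste0(path, ".theta_d")),
                          .cfg_num(spec$n_d, paste0(path, ".n_d")),
                          sigma = sigma),
    skew_normal = skew_normal_prior(
      .cfg_num(spec$theta_d, paste0(path, ".theta_d")),
      .cfg_num(spec$n_d, paste0(path, ".n_d")),
      .cfg_num(spec$lambda, paste0(path, ".lambda")), sigma = sigma),
    trunc_normal = trunc_normal_prior(
      .cfg_num(spec$theta_d, paste0(path, ".theta_d")),
      .cfg_num(spec$n_d, paste0(path, ".n_d")),
      lower = .cfg_num(spec$lower, paste0(path, ".lower")),
      upper = .cfg_num(spec$upper, paste0(path, ".upper"), Inf),
      sigma = sigma),
    mixture = {
      if (length(spec$components) != 2L)
        .cfg_fail(paste0(path, ".components"), "exactly two components")
      cmp <- lapply(seq_len(2L), function(h)
        normal_prior(.cfg_num(spec$components[[h]]$theta_d,
                              sprintf("%s.components[%d].theta_d", path, h)),
                     .cfg_num(spec$components[[h]]$n_d,
                              sprintf("%s.components[%d].n_d", path, h)),
                     sigma = sigma))
      mixture_prior(.cfg_num(spec$w0, paste0(path, ".w0")), cmp[[1]], cmp[[2]])
    },
    .cfg_fail(paste0(path, ".type"), paste("unknown prior type:", spec$type)))
  vp <- NULL
  if (!is.null(spec$variance_prior)) {
    if (spec$type != "normal")
      .cfg_fail(paste0(path, ".variance_prior"),
                "variance priors combine with normal priors only")
    vp <- inv_gamma_prior(
      .cfg_num(spec$variance_prior$shape, paste0(path, ".variance_prior.shape")),
      .cfg_num(spec$variance_prior$scale, paste0(path, ".variance_prior.scale")))
  }
  label <- if (!is.null(spec$label)) spec$label else
    switch(spec$type,
           point = sprintf("point(%g)", spec$theta_d),
           normal = sprintf("normal(%g,%g)%s", spec$theta_d, spec$n_d,
                            if (is.null(vp)) "" else "+IG"),
           skew_normal = sprintf("skew_normal(%g,%g,%g)", spec$theta_d,
                                 spec$n_d, spec$lambda),
           trunc_normal = sprintf("trunc_normal(%g,%g)", spec$theta_d,
                                  spec$n_d),
           mixture = sprintf("mixture(w0=%g)", spec$w0))
  list(prior = pri, vprior = vp, label = label,
       theta_d = if (!is.null(pri$theta_d)) pri$theta_d else NA_real_,
       n_d = if (!is.null(spec$n_d)) spec$n_d else NA_real_)
}

.row_meta <- function(config) {
  data.frame(method = config$evaluation$method,
             M = if (config$evaluation$method == "mc")
                   config$evaluation$M else NA_real_,
             seed = if (is.null(config$evaluation$seed)) NA_real_
                    else config$evaluation$seed,
             version = as.character(packageVersion("posdesign")))
}

#' Evaluate every configured prior at every configured sample size
#'
#' @param config a scenario config (list or JSON path; see [read_scenario()]).
#' @param out optional path: write the result with [write_pos_table()].
#' @return data frame with one row per (prior, n): the four measures, the
#'   decomposition, and full provenance columns. The validated config is
#'   attached as `attr(, "config")`.
#' @export
run_compute <- function(config, out = NULL) {
  config <- read_scenario(config)
  tst <- one_sided_test(config$test$theta0, config$test$alpha,
                        sqrt(config$test$sigma2))
  ev <- config$evaluation
  rows <- list()
  for (ps in config$priors) {
    b <- .build_prior(ps, tst$sigma)
    method <- if (!is.null(b$vprior)) "mc" else ev$method
    for (ni in ev$n) {
      r <- pos(tst, b$prior, ni, method = method, M = ev$M, seed = ev$seed,
               variance_prior = b$vprior)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(prior = b$label, theta_d = b$theta_d, n_d = b$n_d,
                         p0 = r$p0, n = ni, e_a = r$e_a, e_b = r$e_b,
                         e_c = r$e_c, u = r$u, u0 = r$u0, u1 = r$u1),
              .row_meta(config))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(prior = character(0), theta_d = numeric(0),
                     n_d = numeric(0), p0 = numeric(0), n = numeric(0),
                     e_a = numeric(0), e_b = numeric(0), e_c = numeric(0),
                     u = numeric(0), u0 = numeric(0), u1 = numeric(0)),
          .row_meta(config)[0, ])
  attr(res, "config") <- config
  if (!is.null(out)) write_pos_table(res, out)
  res
}

#' Optimal sample sizes for every configured prior and measure
#'
#' Thresholds follow the fraction-of-maximum rule of [pos_thresholds()]
#' unless the config's `ssd` block names explicit per-measure thresholds.
#'
#' @inheritParams run_compute
#' @return data frame with one row per (prior, measure); infeasible requests
#'   are flagged rather than erroring.
#' @export
run_ssd <- function(config, out = NULL) {
  config <- read_scenario(config)
  tst <- one_sided_test(config$test$theta0, config$test$alpha,
                        sqrt(config$test$sigma2))
  sb <- config$ssd
  rows <- list()
  for (ps in config$priors) {
    b <- .build_prior(ps, tst$sigma)
    eps <- pos_thresholds(b$prior, sb$fraction, tst$theta0)
    for (m in sb$measures) {
      r <- pos_ssd(tst, b$prior, measure = m, epsilon = eps[[m]],
                   method = sb$method, M = config$evaluation$M,
                   seed = config$evaluation$seed, n_max = sb$n_max)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(prior = b$label, measure = m, epsilon = eps[[m]],
                         n_star = r$n_star, value = r$value,
                         feasible = r$feasible, reason = r$reason,
                         limit = r$limit),
              .row_meta(config))
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "config") <- config
  if (!is.null(out)) write_pos_table(res, out)
  res
}

#' Long-format measure curves for every configured prior
#'
#' @inheritParams run_compute
#' @param n_grid vector of sample sizes; defaults to the config's
#'   `evaluation$n`.
#' @return data frame with columns `prior`, `measure` (including the
#'   point-mass power curve `eta`), `n`, `value`, plus provenance.
#' @export
run_curves <- function(config, n_grid = NULL, out = NULL) {
  config <- read_scenario(config)
  tst <- one_sided_test(config$test$theta0, config$test$alpha,
                        sqrt(config$test$sigma2))
  ev <- config$evaluation
  if (is.null(n_grid)) n_grid <- ev$n
  rows <- list()
  for (ps in config$priors) {
    b <- .build_prior(ps, tst$sigma)
    cv <- pos_curve(tst, b$prior, n_grid, method = ev$method, M = ev$M,
                    seed = ev$seed)
    for (m in c("eta", "u", "e_a", "e_b", "e_c"))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(prior = b$label, measure = m, n = cv$n,
                         value = cv[[m]]),
              .row_meta(config))
  }
  res <- do.call(rbind, rows)
  attr(res, "config") <- config
  if (!is.null(out)) write_pos_table(res, out)
  res
}

#' Write / read a result table with its provenance header
#'
#' The validated scenario config is echoed verbatim (as one JSON line,
#' prefixed `# config:`) above the CSV header, so a result file can be re-run
#' from its own header; [read_pos_table()] restores both table and config.
#'
#' @param df a data frame from [run_compute()], [run_ssd()] or
#'   [run_curves()].
#' @param path output file.
#' @export
write_pos_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(df, "config")
  if (!is.null(cfg))
    writeLines(paste0("# config: ",
                      jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                       null = "null")), con)
  writeLines(paste0("# posdesign ", as.character(packageVersion("posdesign"))),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pos_table
#' @export
read_pos_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# config: ", lines, value = TRUE)
  df <- read.csv(text = paste(lines[!startsWith(lines, "#")],
                              collapse = "\n"))
  if (length(hdr))
    attr(df, "config") <- jsonlite::fromJSON(sub("^# config: ", "", hdr[1]),
                                             simplifyVector = TRUE,
                                             simplifyDataFrame = FALSE,
                                             simplifyMatrix = FALSE)
  df
}
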
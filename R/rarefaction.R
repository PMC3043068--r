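#' Rarefaction analysis and genome-size estimation
#'
#' Nested subsamples of the read set are assembled and the total assembly
#' size recorded; a saturating model is then fit to estimate the genome
#' size as the curve's asymptote. The default model is an exponential
#' approach `S(d) = G * (1 - exp(-d / kappa))` in the read count `d`; a
#' Michaelis-Menten form `S(d) = G * d / (kappa + d)` is available. The
#' completeness of an assembly is its total bases divided by the fitted
#' `G`.
#'
#' @param reads Sequence-record tibble.
#' @param fractions Sorted sampling fractions in (0, 1] (default 0.05 to
#'   1 in steps of 0.05).
#' @param replicates Subsample replicates per fraction (default 2;
#'   fraction 1 runs once).
#' @param assembler Function `reads -> assembly` (default
#'   [greedy_assemble()] with its defaults).
#' @param model `"exponential"` or `"michaelis"`.
#' @param seed Integer seed; subsampling is seeded per (fraction,
#'   replicate).
#' @return A `rarefaction_fit` object: `points` (tibble `fraction`,
#'   `replicate`, `n_reads`, `assembly_bases`), `asymptote` (fitted G, NA
#'   on fit failure), `kappa`, `model`, `fit` (the nls object or NULL),
#'   `residual` (root mean squared residual).
#' @export
rarefy_and_fit <- function(reads, fractions = seq(0.05, 1, by = 0.05),
                           replicates = 2L, assembler = NULL,
                           model = c("exponential", "michaelis"),
                           seed = 1L) {
  model <- match.arg(model)
  if (is.unsorted(fractions) || any(fractions <= 0) || any(fractions > 1)) {
    abort("`fractions` must be sorted, within (0, 1]")
  }
  if (is.null(assembler)) assembler <- greedy_assemble
  n <- nrow(reads)
  pts <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    reps <- if (f >= 1) 1L else replicates
    for (r in seq_len(reps)) {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, sprintf("rarefy_%d_%d", fi, r)))
      k <- max(1L, round(f * n))
      idx <- sort(sample.int(n, k))
      .Random.seed_restore(old)
      asm <- assembler(reads[idx, , drop = FALSE])
      pts[[length(pts) + 1]] <- tibble(
        fraction = f, replicate = r, n_reads = k,
        assembly_bases = sum(nchar(asm$contigs$bases)))
    }
  }
  points <- bind_rows(pts)
  fit_rarefaction(points, model = model)
}

#' @rdname rarefy_and_fit
#' @param points Tibble with `n_reads` and `assembly_bases` columns (as
#'   produced by `rarefy_and_fit()`), fitted directly.
#' @export
fit_rarefaction <- function(points, model = c("exponential", "michaelis")) {
  model <- match.arg(model)
  G0 <- max(points$assembly_bases) * 1.1 + 1
  k0 <- stats::median(points$n_reads)
  # already-saturated data: the plateau is the estimate and the kinetic
  # constant is unidentifiable
  if (sd(points$assembly_bases) < 1e-9 * max(1, mean(points$assembly_bases))) {
    return(structure(list(
      points = points, asymptote = mean(points$assembly_bases),
      kappa = NA_real_, model = model, fit = NULL, residual = 0,
      saturating = TRUE
    ), class = "rarefaction_fit"))
  }
  form <- if (model == "exponential") {
    assembly_bases ~ G * (1 - exp(-n_reads / kappa))
  } else {
    assembly_bases ~ G * n_reads / (kappa + n_reads)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = points,
                      start = list(G = G0, kappa = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && all(is.finite(coef(fit))) && coef(fit)[["G"]] > 0
  structure(list(
    points = points,
    asymptote = if (ok) unname(coef(fit)[["G"]]) else NA_real_,
    kappa = if (ok) unname(coef(fit)[["kappa"]]) else NA_real_,
    model = model,
    fit = if (ok) fit else NULL,
    residual = if (ok) sqrt(mean(residuals(fit)^2)) else NA_real_,
    saturating = ok
  ), class = "rarefaction_fit")
}

#' @export
print.rarefaction_fit <- function(x, ...) {
  cat(sprintf("<rarefaction_fit> %s model, %d points\n", x$model,
              nrow(x$points)))
  if (x$saturating) {
    cat(sprintf("  asymptote (genome size estimate): %s bases\n",
                format(round(x$asymptote), big.mark = ",")))
  } else {
    cat("  fit failed: non-saturating data, asymptote undefined\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.rarefaction_fit <- function(x, ...) {
  if (!x$saturating || is.null(x$fit)) {
    return(tibble(term = c("G", "kappa"), estimate = NA_real_,
                  std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @importFrom generics glance
#' @export
glance.rarefaction_fit <- function(x, ...) {
  tibble(asymptote = x$asymptote, kappa = x$kappa, model = x$model,
         residual = x$residual, n_points = nrow(x$points),
         saturating = x$saturating)
}

#' Completeness of an assembly against a rarefaction genome-size estimate
#'
#' @param assembly An [new_assembly()].
#' @param fit A `rarefaction_fit`.
#' @return Fraction `assembly bases / fitted asymptote`.
#' @export
completeness <- function(assembly, fit) {
  if (!fit$saturating) return(NA_real_)
  sum(nchar(assembly$contigs$bases)) / fit$asymptote
}

#' @rdname rarefy_and_fit
#' @param object A `rarefaction_fit`.
#' @param ... Ignored.
#' @export
autoplot.rarefaction_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$n_reads,
                                    y = .data$assembly_bases)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "reads sampled", y = "assembly bases",
                  title = "Rarefaction of assembly size")
  if (object$saturating && !is.null(object$fit)) {
    grid <- tibble(n_reads = seq(0, max(object$points$n_reads),
                                 length.out = 200))
    grid$assembly_bases <- predict(object$fit, newdata = grid)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = object$asymptote,
                          linetype = "dashed", colour = "grey40")
  }
  p
}
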
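#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted CSP-PE model
#'
#' One row per pairwise filter with the generalized eigenvalue (the
#' contrast achieved between the two classes: 0.5 means indistinguishable,
#' values near 1 a sharp contrast).
#'
#' @param x a fitted `csp_pe`.
#' @param ... unused.
#' @return A tibble `class_a`, `class_b`, `lambda`, `norm_a`, `norm_b`.
#' @method tidy csp_pe
#' @export
tidy.csp_pe <- function(x, ...) {
  purrr::map_dfr(x$filters, function(f) {
    tibble::tibble(class_a = f$class_a, class_b = f$class_b,
                   lambda = f$lambda, norm_a = f$norm_a, norm_b = f$norm_b)
  })
}

#' @rdname tidy.csp_pe
#' @method glance csp_pe
#' @export
glance.csp_pe <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_filters = length(x$filters),
    n_channels = length(x$channel_ids),
    min_lambda = min(vapply(x$filters, `[[`, numeric(1), "lambda")),
    mean_lambda = mean(vapply(x$filters, `[[`, numeric(1), "lambda"))
  )
}

#' Tidy a fitted LDA decoder
#'
#' @param x a fitted `lda_decoder`.
#' @param ... unused.
#' @return `tidy()`: long tibble of class means per channel;
#'   `glance()`: one-row model summary.
#' @method tidy lda_decoder
#' @export
tidy.lda_decoder <- function(x, ...) {
  m <- x$means
  tibble::tibble(
    class = rep(rownames(m), ncol(m)),
    channel = rep(x$channel_ids, each = nrow(m)),
    mean = as.vector(m)
  )
}

#' @rdname tidy.lda_decoder
#' @method glance lda_decoder
#' @export
glance.lda_decoder <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_channels = nrow(x$coef),
    log_det_cov = determinant(x$pooled_cov)$modulus[1]
  )
}

#' Tidy a calibrated thresholding decoder
#'
#' @param x a `thr_decoder`.
#' @param ... unused.
#' @return One row per movement: subset size, threshold, MVC scale,
#'   calibration quality and the `controllable` flag.
#' @method tidy thr_decoder
#' @export
tidy.thr_decoder <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    class = tab$class,
    n_subset_channels = lengths(tab$channels),
    threshold = tab$threshold,
    mvc = tab$mvc,
    balanced_accuracy = tab$balanced_accuracy,
    recall = tab$recall,
    controllable = tab$controllable
  )
}

#' @rdname tidy.thr_decoder
#' @method glance thr_decoder
#' @export
glance.thr_decoder <- function(x, ...) {
  tibble::tibble(
    n_movements = nrow(x$table),
    n_uncontrollable = sum(!x$table$controllable)
  )
}
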
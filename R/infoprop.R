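# Information propagation metrics: template -> product distributions,
# per-template accuracy, and the mutual information of copying.

#' Build a template x product confusion matrix from endpoint concentrations
#'
#' Each row (one template condition) is normalized over the formed dimers,
#' i.e. the distribution conditions on product formation; unreacted
#' material does not enter. Rows whose total formed product falls below
#' `min_total` are rejected (dropped with a warning).
#'
#' @param endpoints Matrix (templates x products) of endpoint product
#'   concentrations (nM), with dimnames.
#' @param min_total Minimum total product per row (nM, default 0.1).
#' @return A `confusion_matrix`: list(templates, products, p (row
#'   -stochastic matrix), source).
#' @export
product_distribution <- function(endpoints, min_total = 0.1) {
  stopifnot(is.matrix(endpoints), !is.null(rownames(endpoints)),
            !is.null(colnames(endpoints)))
  if (any(endpoints < 0)) stop("concentrations must be >= 0", call. = FALSE)
  tot <- rowSums(endpoints)
  zero <- tot == 0
  if (any(zero))
    stop("no product formed for template(s): ",
         paste(rownames(endpoints)[zero], collapse = ", "), call. = FALSE)
  low <- tot < min_total
  if (any(low)) {
    warning("rejecting template row(s) below min_total: ",
            paste(rownames(endpoints)[low], collapse = ", "))
    endpoints <- endpoints[!low, , drop = FALSE]
    tot <- tot[!low]
  }
  if (!nrow(endpoints)) stop("all rows rejected", call. = FALSE)
  structure(list(templates = rownames(endpoints),
                 products = colnames(endpoints),
                 p = endpoints / tot, source = endpoints),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from a row-stochastic matrix
#'
#' @param p Row-stochastic matrix with dimnames (rows: templates).
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(p) {
  stopifnot(is.matrix(p))
  if (is.null(rownames(p))) rownames(p) <- paste0("t", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- paste0("p", seq_len(ncol(p)))
  if (any(p < 0)) stop("entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-9))
    stop("rows must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(templates = rownames(p), products = colnames(p), p = p,
                 source = NULL),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: %d templates x %d products>\n",
              nrow(x$p), ncol(x$p)))
  print(round(x$p, 3))
  invisible(x)
}

# map template labels onto product labels ("T13" -> "M1N3"; identical
# labels pass through)
template_to_product <- function(templates, products) {
  if (all(templates %in% products)) return(templates)
  m <- regmatches(templates, regexec("^T(\\d)(\\d)$", templates))
  conv <- vapply(m, function(g) {
    if (length(g) == 3L) sprintf("M%sN%s", g[2L], g[3L]) else NA_character_
  }, character(1L))
  if (anyNA(conv) || !all(conv %in% products))
    stop("template labels do not map onto product labels", call. = FALSE)
  conv
}

#' Per-template copying accuracy
#'
#' The percentage of formed product that is the template's intended dimer:
#' the matched entry of each row, times 100.
#'
#' @param cm A `confusion_matrix`.
#' @return List with `per_template` (named %, one per template), `min` and
#'   `mean`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  target <- template_to_product(cm$templates, cm$products)
  per <- 100 * cm$p[cbind(seq_along(cm$templates),
                          match(target, cm$products))]
  names(per) <- cm$templates
  list(per_template = per, min = min(per), mean = mean(per))
}

#' Mutual information between template identity and product identity
#'
#' Plug-in estimator
#' `I = sum_t pi_t sum_p P(p|t) log2( P(p|t) / sum_t' pi_t' P(p|t') )`
#' with the convention `0 log 0 = 0`. For perfect copying over n templates
#' this equals `log2(n)` (3.17 bits for n = 9).
#'
#' @param cm A `confusion_matrix`.
#' @param prior Template distribution (defaults to uniform); must sum to 1
#'   and match the number of templates.
#' @param unidentifiable How products flagged unidentifiable upstream were
#'   handled (`"none"`, `"excluded"` or `"imputed"`); recorded, not acted
#'   on.
#' @return An `mi_result`: list(bits, prior, unidentifiable).
#' @export
mutual_information <- function(cm, prior = NULL,
                               unidentifiable = c("none", "excluded",
                                                  "imputed")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  unidentifiable <- match.arg(unidentifiable)
  nt <- nrow(cm$p)
  if (is.null(prior)) prior <- rep(1 / nt, nt)
  if (length(prior) != nt || any(prior < 0) || abs(sum(prior) - 1) > 1e-9)
    stop("'prior' must be a distribution over the templates", call. = FALSE)
  marg <- drop(prior %*% cm$p)
  bits <- 0
  for (t_ in seq_len(nt)) {
    row <- cm$p[t_, ]
    nz <- row > 0
    bits <- bits + prior[t_] * sum(row[nz] * log2(row[nz] / marg[nz]))
  }
  structure(list(bits = bits, prior = prior, unidentifiable = unidentifiable),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result: %.3f bits>\n", x$bits))
  invisible(x)
}

#' Write / read a confusion matrix as CSV
#'
#' Templates as rows (first column `template`), products as columns.
#'
#' @param cm A `confusion_matrix`.
#' @param path File path.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(template = cm$templates,
                   format(cm$p, digits = 12), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  p <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(p) <- "double"
  rownames(p) <- df$template
  confusion_matrix(p)
}
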
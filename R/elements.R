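# Classification units: one SPD matrix + its degrees of freedom + a label.
# Plus delimited-text readers/writers for element sets.

#' Create an element sample
#'
#' One classification unit: a covariance or correlation matrix, the number of
#' observations it was computed from (its Wishart degrees of freedom), and an
#' optional class label. Elements with `dof < p` cannot be scored — the scale
#' matrix density is undefined when the number of features exceeds the
#' sampling — so they are rejected here.
#'
#' @param matrix `spd_matrix` or square numeric matrix.
#' @param dof integer number of observation vectors behind the matrix
#'   (`dof >= p`).
#' @param label class label (character scalar) or `NA` for unlabeled.
#' @param element_id unique identifier; defaults to an anonymous id.
#' @param ... passed to [validate_spd()] (e.g. `ridge`).
#' @return An object of class `element_sample`.
#' @export
element_sample <- function(matrix, dof, label = NA_character_,
                           element_id = NULL, ...) {
  m <- as_spd(matrix, ...)
  dof <- check_dof(dof, m$p)
  structure(
    list(matrix = m, dof = dof,
         label = as.character(label),
         element_id = as.character(element_id %||% next_element_id())),
    class = "element_sample"
  )
}

.ws_state <- new.env(parent = emptyenv())

next_element_id <- function() {
  n <- (.ws_state$counter %||% 0L) + 1L
  .ws_state$counter <- n
  sprintf("el_%06d", n)
}

#' @export
print.element_sample <- function(x, ...) {
  cat(sprintf("<element_sample> id=%s label=%s p=%d dof=%d\n",
              x$element_id, x$label, x$matrix$p, x$dof))
  invisible(x)
}

element_labels <- function(elements) {
  vapply(elements, function(e) e$label, character(1))
}

element_ids <- function(elements) {
  vapply(elements, function(e) e$element_id, character(1))
}

check_elements <- function(elements, require_labels = FALSE) {
  if (!length(elements)) abort_ws("empty_class_error", "no elements supplied")
  if (!all(vapply(elements, inherits, logical(1), "element_sample"))) {
    abort_ws("domain_error", "all inputs must be element_sample objects")
  }
  dims <- vapply(elements, function(e) e$matrix$p, integer(1))
  if (length(unique(dims)) != 1L) {
    abort_ws("dimension_mismatch_error",
             sprintf("elements mix dimensions: %s", paste(unique(dims), collapse = ", ")))
  }
  ids <- element_ids(elements)
  if (anyDuplicated(ids)) {
    abort_ws("domain_error", "element ids must be unique")
  }
  if (require_labels && anyNA(element_labels(elements))) {
    abort_ws("unlabeled_element_error", "every element must carry a class label")
  }
  invisible(elements)
}

# ---- delimited-text persistence ---------------------------------------------

lower_triangle_names <- function(nms) {
  p <- length(nms)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  paste0(nms[idx[, "row"]], ".", nms[idx[, "col"]])
}

#' Flatten elements to a lower-triangle table
#'
#' One row per element: `element_id`, `label`, `dof`, then the p(p+1)/2
#' lower-triangle entries (diagonal included) named `<row>.<col>`.
#'
#' @param elements list of `element_sample`.
#' @return A data frame, invertible by [table_to_elements()].
#' @export
elements_to_table <- function(elements) {
  check_elements(elements)
  nms <- feature_names(elements[[1]]$matrix)
  keep <- lower.tri(diag(length(nms)), diag = TRUE)
  vals <- t(vapply(elements, function(e) e$matrix$values[keep],
                   numeric(sum(keep))))
  colnames(vals) <- lower_triangle_names(nms)
  cbind(data.frame(element_id = element_ids(elements),
                   label = element_labels(elements),
                   dof = vapply(elements, function(e) e$dof, integer(1)),
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}

#' Rebuild elements from a lower-triangle table
#'
#' @param df data frame in the layout written by [elements_to_table()].
#' @param ... passed to [element_sample()] (e.g. `ridge`).
#' @return A list of `element_sample`.
#' @export
table_to_elements <- function(df, ...) {
  need <- c("element_id", "label", "dof")
  if (!all(need %in% names(df))) {
    abort_ws("domain_error", "table must have element_id, label and dof columns")
  }
  vcols <- setdiff(names(df), need)
  k <- length(vcols)
  p <- (sqrt(8 * k + 1) - 1) / 2
  if (p != round(p)) {
    abort_ws("domain_error", "value columns do not form a lower triangle")
  }
  p <- as.integer(p)
  diag_pos <- 1L + c(0L, cumsum(seq(p, 2L, length.out = p - 1L)))
  nms <- sub("\\..*$", "", vcols[diag_pos])  # diagonal entries named r.r
  keep <- lower.tri(diag(p), diag = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    m <- matrix(0, p, p, dimnames = list(nms, nms))
    m[keep] <- unlist(df[i, vcols], use.names = FALSE)
    m <- m + t(m) - diag(diag(m))
    element_sample(m, dof = df$dof[i], label = df$label[i],
                   element_id = df$element_id[i], ...)
  })
}

#' Write / read element sets as delimited text
#'
#' `write_elements()` stores a manifest (`manifest.tsv`: element_id, label,
#' dof, path) plus one whitespace-delimited matrix file per element;
#' `read_elements()` reads the same layout back.
#'
#' @param elements list of `element_sample`.
#' @param dir directory to create/populate.
#' @return `write_elements()` the manifest path (invisibly);
#'   `read_elements()` a list of `element_sample`.
#' @export
write_elements <- function(elements, dir) {
  check_elements(elements)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("element_%04d.tsv", seq_along(elements))
  for (i in seq_along(elements)) {
    utils::write.table(elements[[i]]$matrix$values,
                       file.path(dir, paths[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(element_id = element_ids(elements),
                         label = element_labels(elements),
                         dof = vapply(elements, function(e) e$dof, integer(1)),
                         path = paths, stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}

#' @rdname write_elements
#' @param ... passed to [element_sample()] (e.g. `ridge`).
#' @export
read_elements <- function(dir, ...) {
  mf <- if (dir.exists(dir)) file.path(dir, "manifest.tsv") else dir
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = c(element_id = "character",
                                               label = "character"))
  base <- dirname(mf)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(file.path(base, manifest$path[i]),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
    element_sample(m, dof = manifest$dof[i], label = manifest$label[i],
                   element_id = manifest$element_id[i], ...)
  })
}
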
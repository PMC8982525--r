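#' Assemble the QSAR descriptor matrix
#'
#' Joins pharmacophore fit values, LRCF bits and physicochemical
#' descriptors into one dense compounds x descriptors matrix with the
#' activity vector (log(1/IC50), molar). Block column order is fits,
#' LRCF, physchem; rows are aligned on `compound_id` and every table must
#' cover exactly the same compound set.
#'
#' @param fit_table,lrcf_table,physchem_table data.frames whose first
#'   column is `compound_id`; remaining columns are descriptors.
#' @param activities data.frame with columns `compound_id` and either
#'   `log_inv_ic50` or `ic50_M`.
#' @return An object of class `DescriptorMatrix`: list with `ids`,
#'   `values` (numeric matrix), `activity`, `blocks` (named column-count
#'   vector).
#' @export
assemble_matrix <- function(fit_table, lrcf_table, physchem_table,
                            activities) {
  tabs <- list(fits = fit_table, lrcf = lrcf_table, physchem = physchem_table)
  ids <- fit_table$compound_id
  for (nm in names(tabs)) {
    tids <- tabs[[nm]]$compound_id
    if (!setequal(tids, ids) || anyDuplicated(tids)) {
      off <- union(setdiff(ids, tids), setdiff(tids, ids))
      stop("compound_id mismatch in ", nm, " block: ",
           paste(utils::head(off, 10), collapse = ", "))
    }
  }
  aids <- activities$compound_id
  if (!setequal(aids, ids))
    stop("activities cover different compounds: ",
         paste(utils::head(union(setdiff(ids, aids), setdiff(aids, ids)), 10),
               collapse = ", "))
  blocks <- integer()
  mats <- list()
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    m <- as.matrix(t[match(ids, t$compound_id), -1, drop = FALSE])
    storage.mode(m) <- "double"
    mats[[nm]] <- m
    blocks[nm] <- ncol(m)
  }
  values <- do.call(cbind, mats)
  rownames(values) <- ids
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor names across blocks: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values))) stop("descriptor matrix contains missing values")
  act <- activities[match(ids, activities$compound_id), ]
  y <- if ("log_inv_ic50" %in% names(act)) act$log_inv_ic50
       else log_inverse_ic50(act$ic50_M)
  structure(list(ids = ids, values = values, activity = as.numeric(y),
                 blocks = blocks), class = "DescriptorMatrix")
}

#' @export
print.DescriptorMatrix <- function(x, ...) {
  cat(sprintf("<DescriptorMatrix: %d compounds x %d descriptors (%s)>\n",
              length(x$ids), ncol(x$values),
              paste(sprintf("%s %d", names(x$blocks), x$blocks),
                    collapse = ", ")))
  invisible(x)
}

#' Rank-striped train/test split
#'
#' Compounds are ranked by IC50 ascending (most potent first; ties by
#' compound id order) and every fifth compound, starting from the most
#' potent, goes to the external test set. 91 compounds give 19 test / 72
#' train.
#'
#' @param matrix a `DescriptorMatrix`.
#' @param stride take every `stride`-th compound (default 5).
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(matrix, stride = 5L) {
  y <- matrix$activity               # log(1/IC50): high = potent = low IC50
  ord <- order(-y, matrix$ids)       # most potent first
  ranked <- matrix$ids[ord]
  test_idx <- seq(1L, length(ranked), by = stride)
  list(train = ranked[-test_idx], test = ranked[test_idx])
}
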
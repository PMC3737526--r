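# Align a label vector to a set of sample ids.
#
# Accepts a factor/character/numeric vector, either positional (length must
# match `n`) or named by sample id.  Named labels are reordered to `ids`;
# labels for unknown samples are dropped with a warning; samples without a
# label are an error.
align_labels <- function(labels, ids = NULL, n = length(labels),
                         what = "label") {
  if (!is.null(names(labels)) && !is.null(ids)) {
    extra <- setdiff(names(labels), ids)
    if (length(extra))
      warning("dropping ", length(extra), " ", what,
              "(s) for samples absent from the data: ",
              paste(utils::head(extra, 5L), collapse = ", "),
              if (length(extra) > 5L) ", ..." else "", call. = FALSE)
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("sample(s) without a ", what, ": ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..." else "", call. = FALSE)
    labels <- labels[ids]
  } else if (length(labels) != n) {
    stop(what, " vector length (", length(labels),
         ") does not match the number of samples (", n, ")", call. = FALSE)
  }
  if (is.factor(labels)) droplevels(labels) else factor(labels)
}
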
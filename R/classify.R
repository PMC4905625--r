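# Rule-based histological subtype classification of cortical tubers.

#' Classify a tuber into histological type A, B or C
#'
#' Deterministic rule over three features of a tuber: giant-cell density
#' (vimentin, cells/mm2), dysmorphic-neuron density (SMI32, cells/mm2) and
#' the presence of calcifications (eye-scored on H&E). Calcification is
#' the discriminator that defines type C and takes precedence; otherwise a
#' tuber is type B when either density exceeds its cutoff (giant cells
#' > 10/mm2 or dysmorphic neurons > 3/mm2) and type A when both are at or
#' below their cutoffs. The boundaries are inclusive for type A, so the
#' rule partitions every nonnegative input.
#'
#' @param giant_cell_density giant cells per mm2, >= 0.
#' @param dysmorphic_density dysmorphic neurons per mm2, >= 0.
#' @param calcification_present logical.
#' @param gc_cutoff giant-cell cutoff, default 10/mm2.
#' @param dn_cutoff dysmorphic-neuron cutoff, default 3/mm2.
#' @return character vector of labels in `c("A", "B", "C")` (vectorised
#'   over the inputs).
#' @export
classify_tuber <- function(giant_cell_density, dysmorphic_density,
                           calcification_present, gc_cutoff = 10,
                           dn_cutoff = 3) {
  if (any(is.na(giant_cell_density)) || any(is.na(dysmorphic_density)))
    stop("densities must not be missing", call. = FALSE)
  if (any(giant_cell_density < 0) || any(dysmorphic_density < 0))
    stop("densities must be nonnegative", call. = FALSE)
  if (gc_cutoff <= 0 || dn_cutoff <= 0)
    stop("cutoffs must be positive", call. = FALSE)
  ifelse(calcification_present, "C",
         ifelse(giant_cell_density > gc_cutoff |
                  dysmorphic_density > dn_cutoff, "B", "A"))
}

#' Is a sample perituberal cortex?
#'
#' Perituberal cortex is defined by the complete absence of the lesional
#' hallmarks: no giant cells, no dysmorphic neurons, no calcification.
#'
#' @inheritParams classify_tuber
#' @return logical vector.
#' @export
is_perituberal <- function(giant_cell_density, dysmorphic_density,
                           calcification_present) {
  if (any(giant_cell_density < 0) || any(dysmorphic_density < 0))
    stop("densities must be nonnegative", call. = FALSE)
  giant_cell_density == 0 & dysmorphic_density == 0 &
    !calcification_present
}

#' Classify every row of a quantification table
#'
#' Maps the quantification columns onto the classifier features
#' (`vimentin_density` is the giant-cell density, `smi32_density` the
#' dysmorphic-neuron density) and appends a `tuber_type` column.
#'
#' @param df data.frame with columns `vimentin_density`, `smi32_density`
#'   and `calcification_present`.
#' @param gc_cutoff,dn_cutoff classifier cutoffs.
#' @return `df` with an added `tuber_type` column.
#' @export
classify_table <- function(df, gc_cutoff = 10, dn_cutoff = 3) {
  need <- c("vimentin_density", "smi32_density", "calcification_present")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$tuber_type <- classify_tuber(df$vimentin_density, df$smi32_density,
                                  df$calcification_present,
                                  gc_cutoff, dn_cutoff)
  df
}
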
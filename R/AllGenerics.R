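#' @import methods
#' @importFrom stats fisher.test p.adjust t.test pnorm dnorm dbinom pf pt
#'   quantile rbeta rbinom rnorm runif rlnorm median setNames coef resid
#'   fitted lm cor var
#' @importFrom utils head tail read.table write.table
NULL

#' Allele-dosage assay of a genotype container
#'
#' @param x A [GenotypeMatrix] or [SVCohort].
#' @return Integer matrix (sites x samples) of alternate-allele dosages
#'   in \{0, 1, 2\}, with `NA` for missing calls.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Sample group labels of a cohort container
#'
#' @param x A cohort object with per-sample grouping (population, strain
#'   group, ...).
#' @return Character vector, one label per sample/genome.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Presence/absence assay of an occupancy matrix
#'
#' @param x An [OccupancyMatrix].
#' @return Logical matrix (orthogroups x genomes).
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
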
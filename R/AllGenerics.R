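#' @include AllClasses.R
NULL

#' Dosage matrix accessor
#' @param x a GenotypeData object
#' @return numeric matrix of dosages (samples x markers)
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Marker map accessor
#' @param x a GenotypeData object
#' @return data.frame with columns id, chrom, pos, a1, a2
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' Sample identifiers
#' @param x a GenotypeData or GRM object
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Number of markers
#' @param x a GenotypeData object
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Number of samples
#' @param x a GenotypeData or GRM object
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Relationship matrix values
#' @param x a GRM object
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' GRM scaling constant 2 * sum p_i (1 - p_i)
#' @param x a GRM object
#' @export
setGeneric("grmScale", function(x) standardGeneric("grmScale"))

#' Narrow-sense heritability implied by the variance components
#' @param x a VarianceComponents object
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' Predicted genetic values
#' @param x a BlupSolution object
#' @export
setGeneric("geneticValues", function(x) standardGeneric("geneticValues"))

#' Fixed-effect estimates
#' @param x a BlupSolution object
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
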
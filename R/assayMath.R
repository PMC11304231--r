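# Droplet-digital-PCR copy number and LDH cytotoxicity calculators.

#' Poisson mean copies per droplet from ddPCR counts
#'
#' Standard droplet-digital-PCR estimator: with targets Poisson-
#' distributed over droplets, the mean copies per droplet is
#' `lambda = -ln((n_total - n_positive) / n_total)`. A well with every
#' droplet positive is saturated and cannot be quantified.
#'
#' @param nPositive,nTotal Positive and total droplet counts.
#' @param dropletVolume Droplet volume in microlitres; when given, the
#'   concentration `lambda / dropletVolume` (copies/uL) is also
#'   returned.
#' @return List with `lambda` (copies/droplet) and `concentration`
#'   (copies/uL, `NA` without a volume).
#' @examples
#' ddpcrLambda(5000, 10000)$lambda  # log(2)
#' @export
ddpcrLambda <- function(nPositive, nTotal, dropletVolume = NULL) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nPositive < 0 || nPositive > nTotal)
    stop("nPositive must lie in [0, nTotal]")
  if (nPositive == nTotal)
    stop("saturated well: all droplets positive, lambda undefined")
  lambda <- -log((nTotal - nPositive) / nTotal)
  list(lambda = lambda,
       concentration = if (is.null(dropletVolume)) NA_real_
                       else lambda / dropletVolume)
}

#' Transgene copies per genome from paired ddPCR wells
#'
#' Ratio of the target-gene concentration to a single-copy reference
#' gene (RPP30 by convention) measured on the same sample:
#' `copies = (lambda_target / lambda_reference) * referenceCopiesPerGenome`.
#'
#' @param targetPositive,targetTotal Droplet counts of the target well.
#' @param referencePositive,referenceTotal Droplet counts of the
#'   reference-gene well.
#' @param referenceCopiesPerGenome Copies of the reference gene per
#'   genome equivalent (default 1, as for a single-copy gene per
#'   haploid genome; set 2 for a per-diploid-genome convention).
#' @return Estimated transgene copies per genome.
#' @export
copiesPerGenome <- function(targetPositive, targetTotal,
                            referencePositive, referenceTotal,
                            referenceCopiesPerGenome = 1) {
  lt <- ddpcrLambda(targetPositive, targetTotal)$lambda
  lr <- ddpcrLambda(referencePositive, referenceTotal)$lambda
  if (lr == 0) stop("no genomes detected: reference well all-negative")
  (lt / lr) * referenceCopiesPerGenome
}

#' LDH-release cytotoxicity percentage
#'
#' `100 * (A_treated - A_control) / (A_max - A_control)` where
#' `A_control` is the spontaneous-release (blank) absorbance and
#' `A_max` the maximum-enzyme-activity absorbance of the target cells.
#'
#' @param aTreated,aControl,aMax Absorbance readings.
#' @return Cytotoxicity in percent.
#' @examples
#' cytotoxicityPct(0.8, 0.2, 1.2)  # 60
#' @export
cytotoxicityPct <- function(aTreated, aControl, aMax) {
  if (isTRUE(all.equal(aMax, aControl)))
    stop("undefined: maximum-activity and control absorbances coincide")
  100 * (aTreated - aControl) / (aMax - aControl)
}
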
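#' @include AllClasses.R
NULL

#' Reference ECS parameter summaries for rat study groups
#'
#' Published-style group summaries (mean, SD, n = 6 animals per group) of the
#' four tracer-MRI ECS parameters in a 6-OHDA rat model of Parkinson's
#' disease: a sham-lesioned group, the lesioned (PD) group, a lesioned group
#' with implanted but unstimulated electrodes (NST), and a lesioned group
#' treated with subthalamic deep-brain stimulation (ST). D* and k' are on
#' the conventional reporting scale (see [internalToReportedD()]), T1/2 in
#' minutes, alpha in percent. These rows are the default ground-truth
#' presets of [defaultDesigns()] and the canonical input of the
#' summary-statistics layer.
#'
#' @return data.frame with columns `group`, `parameter`, `mean`, `sd`, `n`
#' @seealso [referenceAssaySummaries()], [defaultDesigns()]
#' @examples
#' subset(referenceECSSummaries(), parameter == "Dstar")
#' @export
referenceECSSummaries <- function() {
  groups <- c("sham", "pd", "nst", "st")
  tab <- rbind(
    data.frame(group = groups, parameter = "Dstar",
               mean = c(3.09, 4.21, 4.12, 3.74),
               sd   = c(0.08, 0.13, 0.19, 0.27)),
    data.frame(group = groups, parameter = "Thalf",
               mean = c(70.33, 114.40, 113.20, 96.47),
               sd   = c(9.66, 7.16, 6.01, 5.89)),
    data.frame(group = groups, parameter = "kprime",
               mean = c(3.11, 2.28, 2.38, 2.82),
               sd   = c(0.05, 0.08, 0.28, 0.17)),
    data.frame(group = groups, parameter = "alpha",
               mean = c(17.10, 18.03, 17.82, 17.48),
               sd   = c(0.08, 0.15, 0.22, 0.17)))
  tab$n <- 6L
  tab
}

#' Reference molecular-assay summaries for rat study groups
#'
#' Published-style group summaries (mean, SD, n = 6) of the molecular
#' readouts accompanying the ECS parameters in the same rat study design:
#' EAAT2 glutamate-transporter expression (Western blot ratio),
#' extracellular glutamate (microdialysis), hyaluronic-acid ratio (ELISA),
#' AQP-4 and GFAP immunofluorescence densities, and alpha-synuclein
#' immunohistochemistry, for the sham, PD and ST groups.
#'
#' @return data.frame with columns `group`, `assay`, `mean`, `sd`, `n`
#' @seealso [referenceECSSummaries()]
#' @export
referenceAssaySummaries <- function() {
  groups <- c("sham", "pd", "st")
  tab <- rbind(
    data.frame(group = groups, assay = "EAAT2",
               mean = c(1.82, 0.53, 1.68), sd = c(0.54, 0.32, 0.50)),
    data.frame(group = groups, assay = "glutamate",
               mean = c(0.27, 2.31, 0.75), sd = c(0.14, 0.82, 0.36)),
    data.frame(group = groups, assay = "HA",
               mean = c(1.0, 0.53, 0.79), sd = c(0.098, 0.089, 0.065)),
    data.frame(group = groups, assay = "AQP4",
               mean = c(101.5, 63.3, 89.85), sd = c(2.018, 6.343, 4.501)),
    data.frame(group = groups, assay = "GFAP",
               mean = c(82.36, 115.9, 93.24), sd = c(6.037, 8.18, 4.303)),
    data.frame(group = groups, assay = "aSyn",
               mean = c(57.34, 104.7, 70.65), sd = c(5.948, 28.78, 3.587)))
  tab$n <- 6L
  tab
}
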
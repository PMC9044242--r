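#' Published benchmark metrics for the RCA-regularized model
#'
#' Reported evaluation metrics of the double-branch fusion U-Net trained
#' with RCA on the DRIVE, STARE and CHASE benchmarks (FOV-restricted,
#' pooled over test images; gray threshold selected on validation F1).
#' Shipped so that metric self-consistency -- e.g. recomputing G-mean from
#' the reported Se and Sp -- can be checked against the package's own
#' metric implementations.
#'
#' @return data.frame with columns `dataset`, `threshold`, `acc`, `se`,
#'   `sp`, `f1`, `g`, `mcc`, `auc`.
#' @examples
#' b <- publishedBenchmarks()
#' sqrt(b$se * b$sp)  # reproduces the g column
#' @export
publishedBenchmarks <- function() {
  utils::read.csv(system.file("extdata", "published_rca_benchmarks.csv",
                              package = "vesselseg"))
}
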
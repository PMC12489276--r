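#' algaeGEM: refinement and flux analysis of algal genome-scale metabolic models
#'
#' Tools for turning an uncompartmentalized draft metabolic network into a
#' functional, compartmentalized, thermodynamically consistent and
#' enzyme-constrained genome-scale model, plus the flux analyses used to
#' screen gene targets for growth improvement in green algae. See the
#' methods vignette for the underlying models and assumptions.
#'
#' @name algaeGEM-package
#' @aliases algaeGEM
#' @useDynLib algaeGEM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt p.adjust t.test runif setNames
#' @importFrom utils head read.delim write.table
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  # prefer the python on PATH (carries scipy/HiGHS) unless the user pinned one
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON", unset = ""))) {
    exe <- Sys.which("python")
    if (nzchar(exe)) Sys.setenv(RETICULATE_PYTHON = exe)
  }
  invisible()
}
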
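#' Unit conversions used at configuration interfaces
#'
#' All internal computation is SI (meters, tesla, A/m, Hz). Configuration
#' files and user-facing interfaces accept gauss and micrometers, the units
#' in which chip designs and drive fields are usually quoted.
#'
#' @param g Field in gauss.
#' @param t Field in tesla.
#' @return Converted numeric vector.
#' @examples
#' gauss_to_tesla(30)   # 3 mT
#' tesla_to_gauss(3.5e-3)
#' @export
gauss_to_tesla <- function(g) g * 1e-4

#' @rdname gauss_to_tesla
#' @export
tesla_to_gauss <- function(t) t * 1e4

# micrometer <-> meter helpers (internal)
.um <- function(x) x * 1e-6
.to_um <- function(x) x * 1e6
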
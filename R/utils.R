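# Internal geometry and validation helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

vnorm <- function(v) sqrt(sum(v * v))

#' Normalise a 3-vector to unit length
#' @param v numeric length-3 vector.
#' @return unit vector in the direction of `v`.
#' @keywords internal
unit_vector <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3L, all(is.finite(v)))
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Chemical kind vocabulary. The first six are pigments, the next three
# thylakoid lipids; OTHER is a catch-all for mapped but uncounted residues.
PIGMENT_KINDS <- c("CHL_A", "CHL_C", "ALX", "ACAR", "CRO", "MON")
LIPID_KINDS   <- c("LMG", "SQD", "LHG")
ALL_KINDS     <- c(PIGMENT_KINDS, LIPID_KINDS, "OTHER")
CHL_KINDS     <- c("CHL_A", "CHL_C")

kind_label_prefix <- c(
  CHL_A = "a", CHL_C = "c", ALX = "Alx", ACAR = "Car", CRO = "Cro", MON = "Mon"
)
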
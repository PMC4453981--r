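# The YAML analysis parameter bundle. Blocks: wide, rg, rxs1/rxs2 (optional as
# a pair, elongated molecules only), sphere, hydrate, curve, rfac. Q values in
# nm^-1, lengths in nm, divergence in radians, spread as a fraction.

PARAM_SCHEMA <- list(
  wide    = c(qmin = "float", qmax = "float"),
  rg      = c(qmin = "float", qmax = "float",
              fitmin = "float", fitmax = "float"),
  rxs1    = c(qmin = "float", qmax = "float",
              fitmin = "float", fitmax = "float"),
  rxs2    = c(qmin = "float", qmax = "float",
              fitmin = "float", fitmax = "float"),
  sphere  = c(cutoff = "int", boxside = "float"),
  hydrate = c(positions = "int", cutoff = "int"),
  curve   = c(qmax = "float", npoints = "int", radbins = "int",
              smear = "bool"),
  rfac    = c(qmin = "float", qmax = "float"))

OPTIONAL_BLOCKS <- c("rxs1", "rxs2")
SMEAR_FIELDS <- c("wavelength", "spread", "divergence")

check_field <- function(x, block, field, type) {
  label <- paste0(block, ".", field)
  if (is.null(x[[block]]) && !(block %in% OPTIONAL_BLOCKS))
    stop("params: missing required block '", block, "'")
  v <- x[[block]][[field]]
  if (is.null(v)) stop("params: missing required field '", label, "'")
  if (length(v) != 1L) stop("params: field '", label, "' must be a scalar")
  ok <- switch(type,
               float = is.numeric(v) && is.finite(v),
               int = is.numeric(v) && is.finite(v) && v == round(v),
               bool = is.logical(v))
  if (!ok) stop("params: field '", label, "' has wrong type (expected ", type,
                ")")
  if (type == "int") as.integer(v) else v
}

#' Validate an analysis parameter bundle
#'
#' Checks the nested list read from the YAML parameter file against the full
#' schema (blocks `wide`, `rg`, `rxs1`/`rxs2`, `sphere`, `hydrate`, `curve`,
#' `rfac`) and its invariants: `qmin < qmax` and `fitmin < fitmax` within each
#' block, `npoints >= 2`, `radbins >= 1`, positive box side, cutoffs `>= 1`,
#' and -- when `curve.smear` is true -- positive `wavelength`, `spread` and
#' `divergence`. The `rxs1` and `rxs2` blocks are optional but must appear
#' together (cross-sectional analyses of elongated molecules). The 26-position
#' hydration shell is the only supported geometry, so `hydrate.positions` must
#' be 26.
#'
#' @param x nested named list, one entry per block.
#' @return validated object of class `sas_params`.
#' @seealso [read_params()]
#' @export
sas_params <- function(x) {
  if (!is.list(x)) stop("params: input must be a named list of blocks")
  have_rxs <- c("rxs1", "rxs2") %in% names(x)
  if (xor(have_rxs[1], have_rxs[2]))
    stop("params: blocks 'rxs1' and 'rxs2' are optional but must be ",
         "supplied together")
  out <- list()
  for (block in names(PARAM_SCHEMA)) {
    if (block %in% OPTIONAL_BLOCKS && is.null(x[[block]])) next
    fields <- PARAM_SCHEMA[[block]]
    out[[block]] <- lapply(seq_along(fields), function(k)
      check_field(x, block, names(fields)[k], fields[[k]]))
    names(out[[block]]) <- names(fields)
  }
  for (block in intersect(names(out), c("wide", "rg", "rxs1", "rxs2", "rfac")))
    if (out[[block]]$qmin >= out[[block]]$qmax)
      stop("params: ", block, ".qmin must be < ", block, ".qmax")
  for (block in intersect(names(out), c("rg", "rxs1", "rxs2")))
    if (out[[block]]$fitmin >= out[[block]]$fitmax)
      stop("params: ", block, ".fitmin must be < ", block, ".fitmax")
  if (out$sphere$cutoff < 1L) stop("params: sphere.cutoff must be >= 1")
  if (out$sphere$boxside <= 0) stop("params: sphere.boxside must be positive")
  if (out$hydrate$positions != 26L)
    stop("params: hydrate.positions must be 26 (cubic-shell hydration is the ",
         "only supported geometry)")
  if (out$hydrate$cutoff < 1L) stop("params: hydrate.cutoff must be >= 1")
  if (out$curve$qmax <= 0) stop("params: curve.qmax must be positive")
  if (out$curve$npoints < 2L) stop("params: curve.npoints must be >= 2")
  if (out$curve$radbins < 1L) stop("params: curve.radbins must be >= 1")
  if (isTRUE(out$curve$smear)) {
    for (f in SMEAR_FIELDS) {
      v <- x$curve[[f]]
      if (is.null(v))
        stop("params: curve.smear is true but smearing field 'curve.", f,
             "' is missing")
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("params: smearing field 'curve.", f, "' must be a positive ",
             "number")
      out$curve[[f]] <- v
    }
  }
  structure(out, class = "sas_params")
}

#' Read the YAML analysis parameter file
#'
#' @param path path to a YAML file with the blocks described in [sas_params()].
#' @return validated `sas_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("read_params: file not found: ", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("read_params: cannot parse '", path,
                                         "': ", conditionMessage(e)))
  sas_params(y)
}

#' @export
print.sas_params <- function(x, ...) {
  cat("sas_params:\n")
  for (block in names(x)) {
    vals <- vapply(x[[block]], function(v) format(v), character(1))
    cat(sprintf("  %-7s %s\n", block,
                paste(names(x[[block]]), vals, sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Theoretical curve Q grid implied by the parameter bundle
#'
#' `curve.npoints` equally spaced points on `(0, curve.qmax]`; Q = 0 is
#' excluded (the Debye terms are handled by their series limits near zero).
#'
#' @param params a `sas_params` object.
#' @return numeric vector of Q values (nm^-1).
#' @export
q_grid <- function(params) {
  stopifnot(inherits(params, "sas_params"))
  seq(params$curve$qmax / params$curve$npoints, params$curve$qmax,
      length.out = params$curve$npoints)
}
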
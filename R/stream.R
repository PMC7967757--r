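#' Per-tonne stream units
#'
#' Closed set of units for stream coefficients, all normalised per tonne of
#' raw material (t_RM, the fish co-stream entering the processing plant).
#'
#' @return Character vector of valid unit identifiers.
#' @export
stream_units <- function() {
  c("kg/tRM", "t/tRM", "kWh/tRM", "m3/tRM")
}

# units that denominate a mass (used for closure checks)
mass_units <- function() c("kg/tRM", "t/tRM")

# factor converting one stream unit to its annual-flow base unit
# (mass -> t, electricity -> kWh, water -> m3) per unit of capacity (t_RM)
.unit_to_annual <- function(unit) {
  switch(unit,
    "kg/tRM"  = list(factor = 1e-3, unit = "t/a"),
    "t/tRM"   = list(factor = 1,    unit = "t/a"),
    "kWh/tRM" = list(factor = 1,    unit = "kWh/a"),
    "m3/tRM"  = list(factor = 1,    unit = "m3/a"),
    stop("unknown stream unit: '", unit, "' (valid: ",
         paste(stream_units(), collapse = ", "), ")", call. = FALSE)
  )
}

#' Create a stream coefficient
#'
#' A stream coefficient is one row of a process balance: a named input or
#' output with a quantity per tonne of raw material.
#'
#' @param name Stream identifier (e.g. `"oil"`, `"steam"`).
#' @param role Either `"input"` or `"output"`.
#' @param quantity Non-negative amount per tonne of raw material.
#' @param unit One of [stream_units()].
#' @return A one-row data frame of class `stream_coefficient`.
#' @export
#' @examples
#' stream_coefficient("oil", "output", 187, "kg/tRM")
stream_coefficient <- function(name, role = c("input", "output"), quantity, unit) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(quantity) || length(quantity) != 1L || is.na(quantity) || quantity < 0)
    stop("quantity must be a single non-negative number", call. = FALSE)
  if (!unit %in% stream_units())
    stop("unknown stream unit: '", unit, "' (valid: ",
         paste(stream_units(), collapse = ", "), ")", call. = FALSE)
  out <- data.frame(name = name, role = role, quantity = as.numeric(quantity),
                    unit = unit, stringsAsFactors = FALSE)
  class(out) <- c("stream_coefficient", class(out))
  out
}

#' Assemble a process balance
#'
#' A process balance is the fixed per-tonne coefficient table of one
#' processing concept: everything the plant buys or consumes (inputs) and
#' everything it produces (outputs) per tonne of fish co-stream.
#'
#' @param concept_id One of `"I"`, `"II"`, `"III"`, `"IV"` for the reference
#'   concepts, or any other identifier for synthetic scenarios.
#' @param streams A data frame with columns `name`, `role`, `quantity`,
#'   `unit` (e.g. built by rbinding [stream_coefficient()] rows).
#' @param raw_material Name of the raw-material input stream. Must appear as
#'   an input of 1000 kg/tRM (the normalisation basis).
#' @return A `process_balance` object.
#' @export
process_balance <- function(concept_id, streams, raw_material = "fish_costream") {
  stopifnot(is.character(concept_id), length(concept_id) == 1L)
  streams <- as.data.frame(streams, stringsAsFactors = FALSE)
  need <- c("name", "role", "quantity", "unit")
  if (!all(need %in% names(streams)))
    stop("streams must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  streams <- streams[, need]
  rownames(streams) <- NULL
  obj <- structure(
    list(concept_id = concept_id, streams = streams, raw_material = raw_material),
    class = "process_balance"
  )
  validate_process_balance(obj)
  obj
}

#' Validate a process balance
#'
#' Checks the structural invariants: valid units, non-negative quantities,
#' unique names within a role, exactly one raw-material input of 1000 kg/tRM,
#' and kg-denominated output mass not exceeding kg-denominated input mass
#' (the difference being evaporated water and losses).
#'
#' @param x A `process_balance`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_process_balance <- function(x) {
  s <- x$streams
  if (nrow(s) == 0L) stop("process balance has an empty stream list", call. = FALSE)
  bad <- setdiff(unique(s$unit), stream_units())
  if (length(bad))
    stop("unknown stream unit(s): ", paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  if (any(!is.finite(s$quantity)) || any(s$quantity < 0))
    stop("stream quantities must be finite and non-negative", call. = FALSE)
  if (!all(s$role %in% c("input", "output")))
    stop("stream role must be 'input' or 'output'", call. = FALSE)
  key <- paste(s$role, s$name)
  if (anyDuplicated(key))
    stop("duplicate stream name within a role: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  rm <- s$name == x$raw_material & s$role == "input"
  if (sum(rm) != 1L || s$unit[rm] != "kg/tRM" || s$quantity[rm] != 1000)
    stop("balance must contain exactly one '", x$raw_material,
         "' input of 1000 kg/tRM", call. = FALSE)
  mass_in <- kg_mass(s, "input")
  mass_out <- kg_mass(s, "output")
  if (mass_out > mass_in + 1e-9)
    stop("kg-denominated output mass (", mass_out,
         ") exceeds input mass (", mass_in, ")", call. = FALSE)
  invisible(x)
}

# total kg-denominated mass (in kg/tRM) for one role
kg_mass <- function(streams, role) {
  sel <- streams$role == role & streams$unit == "kg/tRM"
  sum(streams$quantity[sel])
}

#' @export
print.process_balance <- function(x, ...) {
  cat("<process_balance> concept", x$concept_id, "\n")
  print(x$streams, row.names = FALSE)
  cl <- mass_closure(x)
  cat(sprintf("mass closure: %.3f (unaccounted %.1f kg/tRM)\n",
              cl$ratio, cl$unaccounted))
  invisible(x)
}

#' Annualise a process balance
#'
#' Scales every per-tonne coefficient by the plant capacity. Mass streams are
#' converted kg -> t; electricity stays in kWh/a and water in m3/a.
#'
#' @param balance A `process_balance`.
#' @param capacity Plant capacity in tonnes of raw material per year (>= 0).
#' @return A data frame with columns `stream`, `role`, `unit` (annual unit),
#'   `per_tRM` (the original coefficient) and `annual`.
#' @export
#' @examples
#' b <- load_concept("III")$balance
#' annualize(b, 10000)  # oil: 187 kg/tRM -> 1870 t/a
annualize <- function(balance, capacity) {
  stopifnot(inherits(balance, "process_balance"))
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) || capacity < 0)
    stop("capacity must be a single non-negative number", call. = FALSE)
  s <- balance$streams
  conv <- lapply(s$unit, .unit_to_annual)
  data.frame(
    stream = s$name,
    role = s$role,
    unit = vapply(conv, `[[`, "", "unit"),
    per_tRM = s$quantity,
    annual = s$quantity * vapply(conv, `[[`, 0, "factor") * capacity,
    stringsAsFactors = FALSE
  )
}

#' Mass closure of a process balance
#'
#' Ratio of kg-denominated output mass to the raw-material input mass. Values
#' below 1 correspond to evaporated water and process losses; auxiliary
#' chemical inputs (acid, enzyme) are excluded from the denominator so the
#' ratio reads as product yield on the co-stream itself.
#'
#' @param balance A `process_balance`.
#' @return A list with `ratio` (in \[0, 1\]), `mass_in`, `mass_out` and
#'   `unaccounted` (kg/tRM attributed to evaporation/losses).
#' @export
#' @examples
#' mass_closure(load_concept("III")$balance)$ratio  # 0.534
mass_closure <- function(balance) {
  stopifnot(inherits(balance, "process_balance"))
  s <- balance$streams
  rm_in <- s$quantity[s$name == balance$raw_material & s$role == "input"]
  if (length(rm_in) != 1L || rm_in <= 0)
    stop("balance has no material input", call. = FALSE)
  mass_out <- kg_mass(s, "output")
  all_in <- kg_mass(s, "input")
  if (mass_out > all_in + 1e-9)
    stop("material outputs exceed material inputs", call. = FALSE)
  list(ratio = min(mass_out / rm_in, 1),
       mass_in = rm_in,
       mass_out = mass_out,
       unaccounted = max(all_in - mass_out, 0))
}
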
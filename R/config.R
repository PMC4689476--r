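# flat TOML-dialect configuration files: comments (#), optional [sections],
# and `key = value` lines with numbers, quoted strings or booleans

parse_toml_value <- function(raw, key, line) {
  v <- trimws(raw)
  if (grepl("^\\[.*\\]$", v)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
    return(vapply(parts, parse_toml_value, numeric(1), key = key,
                  line = line, USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  if (tolower(v) == "inf") return(Inf)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  stop("config line ", line, ": cannot parse value for key `", key, "`: ", raw,
       call. = FALSE)
}

parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- ""
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln)) stop("config line ", i, ": expected `key = value`: ",
                              lines[i], call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- parse_toml_value(sub("^[^=]*=", "", ln), key, i)
    if (section == "") out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

format_toml_value <- function(v) {
  if (length(v) > 1) {
    return(paste0("[", paste(vapply(v, format_toml_value, character(1)),
                             collapse = ", "), "]"))
  }
  if (is.character(v)) paste0('"', v, '"')
  else if (is.logical(v)) tolower(as.character(v))
  else format(v, digits = 17)
}

#' Read / write physical parameters as a flat config file
#'
#' A flat `key = value` text file (TOML dialect) whose keys match the
#' fields of [physical_params()] exactly. The packaged default
#' (`system.file("config", "table_defaults.toml", package = "smacsim")`)
#' mirrors the literature parameter table.
#'
#' @param path File path.
#' @return For `read_physical_params`, a [physical_params()] object.
#' @export
read_physical_params <- function(path) {
  kv <- parse_toml(path)
  kv <- kv[!vapply(kv, is.list, logical(1))]
  known <- names(formals(physical_params))
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(physical_params, kv)
}

#' @rdname read_physical_params
#' @param params A [physical_params()] object.
#' @export
write_physical_params <- function(params, path) {
  validate_physical_params(params)
  lines <- c("# physical parameters of the synaptic cleft model (SI units)",
             vapply(names(unclass(params)), function(k) {
               paste(k, "=", format_toml_value(params[[k]]))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

run_config_sections <- function() {
  list(
    physical = names(formals(physical_params)),
    grid = c("n", "geometry", "ny"),
    bc = c("variant", "h_edge", "p_edge", "C_edge"),
    ic = names(formals(initial_condition)),
    solver = setdiff(names(formals(solver_config)), "terms"),
    analysis = c("threshold_frac", "no_pattern_frac", "ring_frac",
                 "min_dispersed", "centre_tol", "evaluation_minutes"),
    output = c("path"),
    overrides = c("B", "tau")
  )
}

#' Read a full run configuration
#'
#' Sectioned flat config (`[physical]`, `[grid]`, `[bc]`, `[ic]`,
#' `[solver]`, `[analysis]`, `[output]`, `[overrides]`) resolving to the
#' module configuration objects. Unknown sections or keys are rejected.
#'
#' @param path File path.
#' @return A list with elements `params`, `grid`, `bc`, `ic`, `solver`,
#'   `analysis` (named list), `output` (or NULL), `overrides` (B/tau or
#'   NULL), and `raw` (the parsed key-values).
#' @export
read_run_config <- function(path) {
  kv <- parse_toml(path)
  spec <- run_config_sections()
  bad_sec <- setdiff(names(kv), names(spec))
  if (length(bad_sec)) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }
  for (s in names(kv)) {
    unknown <- setdiff(names(kv[[s]]), spec[[s]])
    if (length(unknown)) {
      stop("unknown key(s) in [", s, "]: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  params <- do.call(physical_params, kv$physical %||% list())
  gsec <- kv$grid %||% list()
  grid <- make_grid(n = gsec$n %||% 64,
                    geometry = gsec$geometry %||% "disk",
                    ny = gsec$ny %||% gsec$n %||% 64)
  bsec <- kv$bc %||% list()
  bc <- do.call(boundary_condition, bsec)
  ic <- do.call(initial_condition, kv$ic %||% list())
  solver <- do.call(solver_config, kv$solver %||% list())
  list(params = params, grid = grid, bc = bc, ic = ic, solver = solver,
       analysis = kv$analysis %||% list(),
       output = kv$output$path %||% NULL,
       overrides = kv$overrides %||% list(),
       raw = kv)
}

#' Write a run configuration file
#'
#' Serialises module configs back to the sectioned flat format so that the
#' resolved configuration embedded in a run archive can be re-parsed to an
#' identical resolution.
#'
#' @param config A list as returned by [read_run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  emit <- function(section, kv) {
    if (!length(kv)) return(character(0))
    c(paste0("[", section, "]"),
      vapply(names(kv), function(k) paste(k, "=", format_toml_value(kv[[k]])),
             character(1)), "")
  }
  lines <- c(
    emit("physical", unclass(config$params)),
    emit("grid", list(n = config$grid$n, geometry = config$grid$geometry)),
    emit("bc", unclass(config$bc)),
    emit("ic", unclass(config$ic)),
    emit("solver", Filter(Negate(is.null),
                          unclass(config$solver)[setdiff(
                            names(unclass(config$solver)), "terms")])),
    emit("analysis", config$analysis),
    if (!is.null(config$output)) emit("output", list(path = config$output))
      else character(0),
    emit("overrides", config$overrides)
  )
  writeLines(lines, path)
  invisible(path)
}
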
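#' Species registry
#'
#' A small INI file mapping species keys to installed store files, plus an
#' optional default species, so queries can omit an explicit store path. The
#' registry lives in the user configuration directory by default; every
#' function accepts an explicit `registry` path (used by tests and scripts).
#'
#' @param registry path to the registry file; defaults to
#'   `registry.ini` under [tools::R_user_dir()] for this package.
#' @return `read_registry()` returns a list with `entries` (data frame:
#'   `species`, `path`, `source`) and `default_species`.
#' @export
read_registry <- function(registry = default_registry_path()) {
  if (!file.exists(registry)) {
    return(list(entries = data.frame(species = character(), path = character(),
                                     source = character(), stringsAsFactors = FALSE),
                default_species = NA_character_))
  }
  lines <- trimws(readLines(registry, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  entries <- list()
  default_species <- NA_character_
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.na(section) && section != "registry") {
      entries[[length(entries) + 1L]] <<- data.frame(
        species = section, path = cur$path %||% "",
        source = cur$source %||% "user-added", stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      cur <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!is.na(section) && section == "registry" && key == "default_species") {
        default_species <- val
      } else {
        cur[[key]] <- val
      }
    }
  }
  flush()
  entries <- if (length(entries) == 0L) {
    data.frame(species = character(), path = character(), source = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, entries)
  list(entries = entries, default_species = default_species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_registry
#' @export
default_registry_path <- function() {
  file.path(tools::R_user_dir("snpscreen", "config"), "registry.ini")
}

write_registry <- function(reg, registry) {
  dir.create(dirname(registry), showWarnings = FALSE, recursive = TRUE)
  lines <- character()
  if (!is.na(reg$default_species)) {
    lines <- c("[registry]", paste("default_species =", reg$default_species), "")
  }
  for (i in seq_len(nrow(reg$entries))) {
    e <- reg$entries[i, ]
    lines <- c(lines, sprintf("[%s]", e$species),
               paste("path =", e$path), paste("source =", e$source), "")
  }
  writeLines(lines, registry)
  invisible(registry)
}

#' @rdname read_registry
#' @param species species key.
#' @param path store file path for that species.
#' @param source `"prebuilt"` (fetched) or `"user-added"` (built locally).
#' @export
registry_add <- function(species, path, source = "user-added",
                         registry = default_registry_path()) {
  stopifnot(grepl("^[a-z][a-z0-9_]*$", species), nzchar(path))
  reg <- read_registry(registry)
  reg$entries <- reg$entries[reg$entries$species != species, , drop = FALSE]
  clash <- reg$entries$path == path
  if (any(clash)) stop("store path already registered for species ",
                       reg$entries$species[clash][[1L]])
  reg$entries <- rbind(reg$entries,
    data.frame(species = species, path = path, source = source,
               stringsAsFactors = FALSE))
  write_registry(reg, registry)
  invisible(reg)
}

#' @rdname read_registry
#' @export
registry_set_default <- function(species, registry = default_registry_path()) {
  reg <- read_registry(registry)
  if (!species %in% reg$entries$species) {
    stop("species '", species, "' is not registered")
  }
  reg$default_species <- species
  write_registry(reg, registry)
  invisible(reg)
}

#' @rdname read_registry
#' @return `registry_store_path()` returns the store path for a species (or
#'   the default species when `species` is `NULL`).
#' @export
registry_store_path <- function(species = NULL, registry = default_registry_path()) {
  reg <- read_registry(registry)
  if (is.null(species)) species <- reg$default_species
  if (is.na(species) || is.null(species)) stop("no species given and no default set")
  hit <- reg$entries[reg$entries$species == species, , drop = FALSE]
  if (nrow(hit) == 0L) stop("species '", species, "' is not registered")
  hit$path[[1L]]
}

#' Fetch a prebuilt store file
#'
#' Copies (local path) or downloads (URL) a prebuilt store, opens it to check
#' the schema, and registers it for the species.
#'
#' @param location URL or local path of the store file.
#' @param species species key to register it under.
#' @param dest destination file path.
#' @inheritParams read_registry
#' @return invisibly, `dest`.
#' @export
fetch_store <- function(location, species, dest,
                        registry = default_registry_path()) {
  dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
  if (grepl("^[a-z]+://", location)) {
    status <- utils::download.file(location, dest, quiet = TRUE, mode = "wb")
    if (status != 0L) stop("unreachable location: ", location)
  } else {
    if (!file.exists(location)) stop("unreachable location: ", location)
    file.copy(location, dest, overwrite = TRUE)
  }
  st <- open_store(dest, species)  # schema check
  close_store(st)
  registry_add(species, dest, source = "prebuilt", registry = registry)
  invisible(dest)
}
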
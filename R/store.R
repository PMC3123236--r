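# Project store with creator/timestamp auditing and soft deletion.
#
# Layout on disk (when opened with a path):
#   <root>/users.json                   registered users
#   <root>/<type>/<sanitized-name>.json one JSON document per resource
# Every resource document carries schema_version, its class tag and an
# audit block; see docs/formats.md in the source repository.

STORE_SCHEMA_VERSION <- 1L

resource_type <- function(x) {
  cls <- class(x)[1]
  if (!startsWith(cls, "pw_")) stop_validation("not a store resource")
  sub("^pw_", "", cls)
}

STORE_TYPES <- c("plate_type", "plate_layout", "master_plate", "plate",
                 "substance", "sample")

#' Open (or create) a project store
#'
#' The store persists every resource as one JSON document per resource with
#' an audit record (creator, creation time), supports soft deletion with
#' admin-only undelete, and never physically removes anything. With
#' `path = NULL` the store lives in memory only.
#'
#' @param path store root directory, created if missing; `NULL` for an
#'   in-memory store.
#' @return an environment of class `pw_store`.
#' @export
store_open <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$resources <- stats::setNames(vector("list", length(STORE_TYPES)), STORE_TYPES)
  for (t in STORE_TYPES) store$resources[[t]] <- list()
  store$users <- list()
  class(store) <- "pw_store"
  if (!is.null(path)) {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop_io(sprintf("cannot create store directory '%s'", path))
    }
    ufile <- file.path(path, "users.json")
    if (file.exists(ufile)) store$users <- decode_value(jsonlite::read_json(ufile))
    for (t in STORE_TYPES) {
      d <- file.path(path, t)
      if (!dir.exists(d)) next
      for (f in sort(list.files(d, pattern = "\\.json$", full.names = TRUE))) {
        doc <- decode_value(jsonlite::read_json(f))
        res <- doc$resource
        store$resources[[t]][[res$name]] <- res
      }
    }
  }
  store
}

#' @export
print.pw_store <- function(x, ...) {
  counts <- vapply(x$resources, length, integer(1))
  cat(sprintf("<store> %s: %s; %d user(s)\n",
              if (is.null(x$path)) "(in memory)" else x$path,
              paste(sprintf("%d %s", counts, names(counts)), collapse = ", "),
              length(x$users)))
  invisible(x)
}

sanitize_name <- function(name) gsub("[^A-Za-z0-9._-]", "_", name)

persist_resource <- function(store, resource) {
  if (is.null(store$path)) return(invisible(NULL))
  type <- resource_type(resource)
  d <- file.path(store$path, type)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  doc <- list(schema_version = STORE_SCHEMA_VERSION, type = type,
              name = resource$name, resource = resource)
  jsonlite::write_json(encode_value(doc), file.path(d, paste0(sanitize_name(resource$name), ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(NULL)
}

persist_users <- function(store) {
  if (is.null(store$path)) return(invisible(NULL))
  jsonlite::write_json(encode_value(store$users), file.path(store$path, "users.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(NULL)
}

#' Manage store users
#'
#' There are two user levels: administrators and regular users. An
#' administrator can do everything a regular user can, and additionally
#' create users and undelete resources.
#'
#' @param store a [store_open()] store.
#' @param username unique user name.
#' @param role `"regular"` or `"admin"`.
#' @param by the acting user; required (and must be an admin) once the
#'   store has any users.
#' @return the created user record, invisibly.
#' @export
add_user <- function(store, username, role = c("regular", "admin"), by = NULL) {
  stopifnot(inherits(store, "pw_store"))
  assert_scalar_chr(username, "username")
  role <- match.arg(role)
  if (length(store$users) > 0L) {
    if (is.null(by)) stop_permission("adding users requires an admin user")
    actor <- store$users[[by]]
    if (is.null(actor) || actor$role != "admin")
      stop_permission(sprintf("user '%s' is not an administrator", by))
  }
  if (!is.null(store$users[[username]]))
    stop_conflict(sprintf("user '%s' already exists", username))
  store$users[[username]] <- list(username = username, role = role)
  persist_users(store)
  invisible(store$users[[username]])
}

resolve_user <- function(store, user) {
  assert_scalar_chr(user, "user")
  u <- store$users[[user]]
  if (is.null(u)) stop_validation(sprintf("unknown user '%s'", user))
  u
}

#' Save a resource into the store
#'
#' Attaches an audit record (creator and UTC creation timestamp) on first
#' save. Names are unique per resource type among all resources, deleted or
#' not; plates additionally keep barcodes unique among non-deleted plates.
#' Re-saving an existing resource (e.g. after data import or outlier
#' curation) requires `overwrite = TRUE` and never touches the original
#' audit fields.
#'
#' @param store a [store_open()] store.
#' @param resource any `pw_*` resource.
#' @param user acting username (must be registered).
#' @param overwrite allow updating an existing resource of the same name.
#' @return the stored resource (with audit record), invisibly.
#' @export
store_save <- function(store, resource, user, overwrite = FALSE) {
  stopifnot(inherits(store, "pw_store"))
  if (!inherits(resource, "pw_resource")) stop_validation("not a storable resource")
  u <- resolve_user(store, user)
  type <- resource_type(resource)
  existing <- store$resources[[type]][[resource$name]]
  if (!is.null(existing) && !overwrite)
    stop_conflict(sprintf("%s '%s' already exists in the store", type, resource$name))
  if (type == "plate") {
    for (other in store$resources$plate) {
      if (other$name != resource$name && !is_deleted(other) &&
          identical(other$barcode, resource$barcode))
        stop_conflict(sprintf("barcode '%s' is already used by plate '%s'",
                              resource$barcode, other$name))
    }
  }
  if (is.null(existing)) {
    resource$audit <- list(
      creator = u$username,
      created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      deleted = FALSE, deleted_by = NA_character_, deleted_at = NA_character_
    )
  } else {
    resource$audit <- existing$audit  # audit fields never mutate on update
  }
  store$resources[[type]][[resource$name]] <- resource
  persist_resource(store, resource)
  invisible(resource)
}

#' Fetch a resource from the store
#'
#' @param store a [store_open()] store.
#' @param type resource type, one of `plate_type`, `plate_layout`,
#'   `master_plate`, `plate`, `substance`, `sample`.
#' @param name resource name.
#' @param include_deleted also return soft-deleted resources (flagged in
#'   their audit record).
#' @return the resource, or `NULL` if absent (or deleted and
#'   `include_deleted = FALSE`).
#' @export
store_get <- function(store, type, name, include_deleted = FALSE) {
  stopifnot(inherits(store, "pw_store"))
  type <- match.arg(type, STORE_TYPES)
  res <- store$resources[[type]][[name]]
  if (is.null(res)) return(NULL)
  if (is_deleted(res) && !include_deleted) return(NULL)
  res
}

find_plate_by_barcode <- function(store, barcode) {
  for (p in store$resources$plate)
    if (!is_deleted(p) && identical(p$barcode, barcode)) return(p)
  NULL
}

#' Soft-delete and undelete resources
#'
#' For auditability a resource can never be physically removed — deletion
#' only marks it, hiding it from default listings and blocking new
#' references to it. Only an administrator can undelete.
#'
#' @inheritParams store_get
#' @param user acting username; must be an admin for `undelete()`.
#' @return the updated resource, invisibly.
#' @export
soft_delete <- function(store, type, name, user) {
  stopifnot(inherits(store, "pw_store"))
  type <- match.arg(type, STORE_TYPES)
  u <- resolve_user(store, user)
  res <- store$resources[[type]][[name]]
  if (is.null(res)) stop_reference(sprintf("%s '%s' does not exist", type, name))
  if (is_deleted(res)) {
    warning(sprintf("%s '%s' is already deleted", type, name))
    return(invisible(res))
  }
  res$audit$deleted <- TRUE
  res$audit$deleted_by <- u$username
  res$audit$deleted_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  store$resources[[type]][[name]] <- res
  persist_resource(store, res)
  invisible(res)
}

#' @rdname soft_delete
#' @export
undelete <- function(store, type, name, user) {
  stopifnot(inherits(store, "pw_store"))
  type <- match.arg(type, STORE_TYPES)
  u <- resolve_user(store, user)
  if (u$role != "admin")
    stop_permission(sprintf("user '%s' is not an administrator; only admins can undelete", user))
  res <- store$resources[[type]][[name]]
  if (is.null(res)) stop_reference(sprintf("%s '%s' does not exist", type, name))
  if (!is_deleted(res)) {
    warning(sprintf("%s '%s' is not deleted", type, name))
    return(invisible(res))
  }
  res$audit$deleted <- FALSE
  res$audit$deleted_by <- NA_character_
  res$audit$deleted_at <- NA_character_
  store$resources[[type]][[name]] <- res
  persist_resource(store, res)
  invisible(res)
}

#' Hierarchical store listing
#'
#' Lists resources in the plate-design hierarchy (plate type, then the
#' layouts built on it, the master plates on each layout, and the plates of
#' each master), followed by substances and samples. Ordering is
#' deterministic: by type, then name. Deleted resources are hidden unless
#' `all = TRUE`.
#'
#' @param store a [store_open()] store.
#' @param type optional filter to one resource type.
#' @param all include soft-deleted resources (flagged in the `deleted`
#'   column).
#' @return a data frame with columns `type`, `name`, `parent`, `depth`,
#'   `deleted`, `creator`, `created_at`.
#' @export
list_tree <- function(store, type = NULL, all = FALSE) {
  stopifnot(inherits(store, "pw_store"))
  rows <- list()
  add <- function(res, depth, parent) {
    if (is_deleted(res) && !all) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      type = resource_type(res), name = res$name, parent = parent, depth = depth,
      deleted = is_deleted(res),
      creator = if (is.null(res$audit)) NA_character_ else res$audit$creator,
      created_at = if (is.null(res$audit)) NA_character_ else res$audit$created_at,
      stringsAsFactors = FALSE)
  }
  sorted <- function(lst) if (length(lst) == 0L) lst else lst[order(names(lst))]
  for (pt in sorted(store$resources$plate_type)) {
    add(pt, 0L, NA_character_)
    for (lay in sorted(store$resources$plate_layout)) {
      if (lay$plate_type$name != pt$name) next
      add(lay, 1L, pt$name)
      for (mp in sorted(store$resources$master_plate)) {
        if (mp$layout$name != lay$name) next
        add(mp, 2L, lay$name)
        for (pl in sorted(store$resources$plate)) {
          if (pl$master$name != mp$name) next
          add(pl, 3L, mp$name)
        }
      }
    }
  }
  for (s in sorted(store$resources$substance)) add(s, 0L, NA_character_)
  for (s in sorted(store$resources$sample)) add(s, 0L, NA_character_)
  out <- if (length(rows) == 0L) {
    data.frame(type = character(0), name = character(0), parent = character(0),
               depth = integer(0), deleted = logical(0), creator = character(0),
               created_at = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  if (!is.null(type)) out <- out[out$type == type, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- tagged JSON (de)serialization ----------------------------------------
# Generic round-trip encoding: atomic vectors carry their storage type,
# data frames and classed lists carry structural tags.

encode_value <- function(x) {
  if (is.null(x)) return(list(`_type` = "null"))
  if (is.data.frame(x)) {
    return(list(`_type` = "data.frame",
                columns = lapply(as.list(x), encode_value)))
  }
  if (is.list(x)) {
    out <- list(`_type` = "list", items = lapply(unname(x), encode_value))
    if (!is.null(names(x))) out$names <- as.list(names(x))
    cls <- class(x)
    if (!identical(cls, "list")) out$`_class` <- as.list(cls)
    return(out)
  }
  if (is.atomic(x)) {
    vals <- if (is.double(x)) {
      # doubles travel as 17-significant-digit strings for an exact round trip
      lapply(unname(x), function(v) if (is.na(v)) NA else sprintf("%.17g", v))
    } else as.list(unname(x))
    return(list(`_type` = typeof(x), values = vals,
                names = if (is.null(names(x))) NULL else as.list(names(x))))
  }
  stop_io(sprintf("cannot serialize object of type '%s'", typeof(x)))
}

decode_value <- function(x) {
  type <- x[["_type"]]
  if (is.null(type)) stop_io("malformed store document (missing _type)")
  if (type == "null") return(NULL)
  if (type == "data.frame") {
    cols <- lapply(x$columns, decode_value)
    n <- if (length(cols) == 0L) 0L else length(cols[[1]])
    return(structure(cols, names = names(x$columns),
                     row.names = seq_len(n), class = "data.frame"))
  }
  if (type == "list") {
    items <- lapply(x$items, decode_value)
    if (!is.null(x$names)) names(items) <- unlist(x$names)
    if (!is.null(x[["_class"]])) class(items) <- unlist(x[["_class"]])
    return(items)
  }
  vals <- x$values
  vals[vapply(vals, is.null, logical(1))] <- NA
  v <- switch(type,
    double = vapply(vals, as.numeric, numeric(1)),
    integer = vapply(vals, as.integer, integer(1)),
    logical = vapply(vals, as.logical, logical(1)),
    character = vapply(vals, function(e) if (is.na(e[1])) NA_character_ else as.character(e), character(1)),
    stop_io(sprintf("unknown stored type '%s'", type)))
  if (!is.null(x$names)) names(v) <- unlist(x$names)
  v
}
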
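#' Read and write rule-base files
#'
#' One rule per block, blocks separated by blank lines, fields as
#' `key: value` lines (`id`, `dimension`, `priority`, `condition`, `assign`,
#' optional `kind` and `description`). Lines starting with `#` are comments.
#' A `version:` line before the first block tags the base. Writing then
#' reading a base reproduces it bit-exactly.
#'
#' @param path File path.
#' @return `read_rule_base()` returns a [rule_base()].
#' @export
read_rule_base <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  version <- "1"
  blocks <- list()
  cur <- character(0)
  flush <- function() {
    if (length(cur) > 0) blocks[[length(blocks) + 1]] <<- cur
    cur <<- character(0)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) flush() else cur <- c(cur, ln)
  }
  flush()
  rules <- list()
  for (b in blocks) {
    kv <- regmatches(b, regexec("^\\s*([a-z_]+)\\s*:\\s*(.*?)\\s*$", b))
    fields <- stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
    if (identical(names(fields), "version")) {
      version <- fields[["version"]]
      next
    }
    rules[[length(rules) + 1]] <- rule(
      id = fields[["id"]],
      dimension = fields[["dimension"]],
      priority = as.integer(fields[["priority"]]),
      condition = fields[["condition"]],
      assign = fields[["assign"]],
      kind = if ("kind" %in% names(fields)) fields[["kind"]] else "assign",
      description = if ("description" %in% names(fields)) fields[["description"]] else ""
    )
  }
  rule_base(rules, version = version)
}

#' @rdname read_rule_base
#' @param rules A [rule_base()] to serialize.
#' @export
write_rule_base <- function(rules, path) {
  out <- c(paste0("version: ", rules$version))
  for (r in rules$rules) {
    block <- c("",
               paste0("id: ", r$id),
               paste0("dimension: ", r$dimension),
               paste0("priority: ", r$priority),
               paste0("condition: ", r$condition),
               paste0("assign: ", r$assign))
    if (r$kind != "assign") block <- c(block, paste0("kind: ", r$kind))
    if (nzchar(r$description)) block <- c(block, paste0("description: ", r$description))
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(path)
}
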
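#' Read a SMILES file
#'
#' One molecule per line; an optional whitespace-separated name after the
#' SMILES is kept as the vector's names. Blank lines and `#` comments are
#' skipped. An empty string denotes the empty molecule.
#'
#' @param path File path.
#' @return Named character vector of SMILES.
#' @export
read_smiles_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  names(smiles) <- vapply(parts, function(p)
    if (length(p) > 1L) p[2L] else "", character(1))
  smiles
}

#' Read / write a run configuration file
#'
#' A YAML (or JSON) file with up to three top-level blocks: `mdp` (fields of
#' [mdp_config()]), `reward` (fields of [reward_spec()]) and `agent` (fields
#' of [dqn_agent()]). Missing fields fall back to the function defaults; the
#' reward's horizon defaults to the MDP's.
#'
#' @param path Configuration file path.
#' @return A list with elements `config`, `spec`, and `agent_args`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- do.call(mdp_config, raw$mdp %||% list())
  reward_args <- raw$reward %||% list()
  if (is.null(reward_args$max_steps)) reward_args$max_steps <- config$max_steps
  spec <- do.call(reward_spec, reward_args)
  list(config = config, spec = spec, agent_args = raw$agent %||% list())
}

#' @rdname read_run_config
#' @param config An [mdp_config()].
#' @param spec A [reward_spec()].
#' @param agent_args List of [dqn_agent()] arguments.
#' @export
write_run_config <- function(path, config, spec, agent_args = list()) {
  yaml::write_yaml(list(
    mdp = unclass(config),
    reward = Filter(Negate(is.null), unclass(spec)),
    agent = agent_args
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run report as JSON
#' @param report A [run_report()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(list(
    top = report$top, validity = report$validity,
    n_terminals = report$n_terminals,
    terminals = report$terminals, scores = report$scores,
    returns = report$returns
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
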
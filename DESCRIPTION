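Package: abdyn
Title: Mass-Action Models of Antibody Repertoire Dynamics with Somatic
    Hypermutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulators of humoral immune dynamics. A
    single-antibody mass-action model couples antibody, antigen and
    antibody-antigen complex concentrations for a replicating pathogen or a
    constant self-antigen, and explains clonal deletion of strongly
    self-binding antibodies as a kinetic consequence of weak T-helper
    stimulation. A nine-class repertoire model adds somatic hypermutation as
    a transition kernel over discrete binding-affinity classes derived from
    a Normal(-9, 1) distribution of log10 equilibrium dissociation
    constants, and reproduces affinity maturation, self-tolerance and the
    slow drift of the repertoire toward self-reactive classes. Named
    scenario presets encode the published experiments; trajectories,
    summary metrics and the mutation kernel are exported as plain CSV/JSON,
    and a command-line front-end wraps the scenario runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
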
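Package: swarmlearn
Title: Stochastic Dynamics and Reinforcement-Learning Control of Active
    Microswimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for simulating self-propelled microscopic
    particles (active Brownian particles) under overdamped Langevin dynamics
    and for training control policies over them with multi-agent actor-critic
    reinforcement learning. Provides a vectorized Euler-Maruyama engine with
    Weeks-Chandler-Andersen interactions and periodic or reflective
    boundaries, a modular component model (agents, actions, observables,
    tasks, trainers), vanilla policy gradient and proximal policy
    optimization with generalized advantage estimation, categorical and
    Gumbel-trick action sampling, random network distillation for intrinsic
    exploration, and reproducible synthetic fixtures validated against
    closed-form active-matter statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
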
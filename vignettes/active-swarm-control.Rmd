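---
title: "Methods: stochastic dynamics and learned control of active microswimmers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic dynamics and learned control of active microswimmers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmlearn)
```

# The physical model

`swarmlearn` models microswimmers as active Brownian particles (ABPs): each
particle carries a position $\mathbf r_i$ and a unit director $\hat{\mathbf
e}_i$, and evolves in the overdamped limit where friction and noise balance
instantaneously and inertia plays no role. The translational equation of
motion is

$$\dot{\mathbf r}_i = \gamma_t^{-1}\left[F^{\mathrm{act}}_i\,\hat{\mathbf e}_i
 + \mathbf F_i(\mathbf r_i, \{\mathbf r_j\})\right]
 + \sqrt{2 k_B T \gamma_t^{-1}}\;\boldsymbol\xi^t_i,$$

with $\langle \boldsymbol\xi \rangle = 0$ and delta-correlated unit
covariance. All quantities are in reduced units with $k_B = 1$: the
diffusion coefficients are $D_t = T/\gamma_t$ and $D_r = T/\gamma_r$, and
the persistence time of the director is $\tau_r = 1/D_r$.

**Rotational update.** In 2D the director angle $\theta$ performs driven
rotational diffusion,
$\theta \leftarrow \theta + \gamma_r^{-1}(M^{\mathrm{act}} +
M^{\mathrm{int}})\,\Delta t + \sqrt{2 k_B T \gamma_r^{-1}\Delta t}\;\xi_r$,
which is the standard overdamped rotational Langevin form consistent with
the stated noise statistics; in 2D only the out-of-plane torque component
acts, and positive torque rotates counterclockwise (the steering direction
$\hat{\mathbf n}$ is $\hat{\mathbf e}$ rotated by $+90^\circ$, which fixes
the sign of "rotate clockwise" actions). In 3D the director is rotated by
the angular increment vector and renormalized — a small-rotation Euler
scheme whose error is controlled by $\Delta t$, like the rest of the
integrator. Interaction torques $M^{\mathrm{int}}$ are exposed as a hook
but none of the shipped components produce them.

**Integrator.** Euler–Maruyama throughout. For free translational and 2D
rotational diffusion the scheme is exact in distribution per step; for
driven motion the weak error is $O(\Delta t)$. The test suite quantifies
this directly: with $\Delta t = 0.01\,\tau_r$ the active-Brownian MSD
matches its closed form to a fraction of a percent, far inside the 5%
acceptance band.

**Interactions and boundaries.** The only pair interaction is the purely
repulsive Weeks–Chandler–Andersen force, cut off at $2^{1/6}\sigma$;
separations below $0.5\sigma$ indicate an integration step too large for
the stiffness and trigger a capped-force warning rather than a numerical
blow-up (a per-step displacement of $0.1\sigma$ or more also warns).
Hydrodynamic interactions are deliberately absent: the package targets the
dry-active-matter regime. Boundaries are "none" (unbounded), periodic
(minimum-image convention, positions wrapped, unwrapped coordinates kept
alongside for displacement statistics), or reflective. Reflective walls are
implemented as specular reflection — the position is mirrored at the wall
and the director component flipped — rather than a soft harmonic wall,
because reflection keeps the inside-the-box invariant exact and introduces
no stiffness parameter that would itself constrain $\Delta t$.

**Rigid bodies.** The rod of the rotation task is a chain of passive WCA
beads moved as one rigid unit: the net force and net torque on the members
update the body's centre and orientation with body-level frictions, then
bead positions are reconstructed. This is the cheapest rigid object that
pushers can exert a torque on.

# The control model

Control code sees the world only through the *force function*: once per
time slice it receives the full particle table and returns one action per
particle. The chosen action (propulsion force magnitude, torque, or a
direct director override — the override takes precedence over the torque
for that slice) is held constant over all inner integration steps of the
slice. This narrow interface is what makes engines swappable: the 2-armed
bandit used to validate the training mathematics implements the same
two-method contract (`integrate_system`, `get_particle_data`) as the
Langevin engine.

**Observables** condense the state into what a micro-agent could plausibly
sense. The chemotaxis observable returns the *change* in sensed
concentration between slices — a direction-blind scalar, as for a
run-and-tumble bacterium. On the first slice the previous value is
initialized to the current one so the first output is zero; this avoids a
spurious reward at episode start. **Tasks** return one reward per particle
and own the kill switch, a latched flag that stops the engine at the end of
the current slice. Rewards follow the $s_t, a_t \to s_{t+1}, r_{t+1}$
convention: the reward computed at slice $t{+}1$ is attributed to the
action taken at slice $t$, and the final action's reward is filled in from
the post-episode state.

The chemotaxis reward is the *clipped* positive gain $\max(0, \Delta c)$ by
default, mirroring the positive-reinforcement structure of bacterial
chemotaxis; the signed variant is a flag. Clipping removes the penalty for
exploratory down-gradient moves, which in practice stabilizes early
training when almost all moves are down-gradient.

# Training

Returns are $G_t = \sum_{t'} \gamma^{t'-t} r_{t'}$ (exact backward
recursion), advantages $A_t = G_t - V_t$ or GAE($\lambda$) with terminal
bootstrap 0. Two policy updates are provided: vanilla policy gradient
(loss $-\sum_t \log\pi(a_t|s_t) A_t$) and the standard clipped-surrogate
PPO (default $\epsilon_{\mathrm{clip}} = 0.2$, 4 epochs per batch) — the
canonical definitions of the cited methods, since only their names pin them
down. Probabilities are clamped at $10^{-8}$ before any logarithm so all
losses are finite.

Two choices that the framework leaves genuinely open are both configurable
rather than asserted: per-batch advantage standardization (on by default, a
common variance-reduction device; a degenerate batch is only centred, never
divided by a near-zero spread) and an entropy bonus (default coefficient
0.01, flagged clearly as an extension) that delays premature collapse in
small discrete action sets. All particles of a shared-policy group are
pooled into one batch per update (parameter sharing); a team-average reward
mode replaces each particle's reward with the group mean for the
cooperative setting.

The networks are multilayer perceptrons with tanh hidden layers (default
two layers of 128 units, matching the scale at which such policies are
typically run), with either a shared trunk feeding separate actor/critic
heads or fully disjoint actor and critic networks. Backpropagation and the
Adam-style optimizer are implemented in the package; the finite-difference
gradient check in the test suite holds both to $10^{-4}$ relative error.
The plain ascent rule $\theta' = \theta + \eta \nabla_\theta J$ is also
available, and is what the bandit fixture uses: with Adam's step-size
renormalization, the vanishingly small gradients of a saturated softmax are
rescaled to full-size steps, so a converged bandit policy can be walked
back out of its optimum by critic noise — a known pathology, avoided here
by construction in that fixture.

**Exploration.** The random-exploration policy substitutes a uniformly
random action with probability $\zeta' = e^{-\varepsilon t/T}\,\zeta$,
where $t$ is cumulative simulation time and $T$ the duration of one
episode. The log-probability recorded for training is the policy's
log-probability of the *executed* action; whether exploration actions
should instead be excluded from the policy-gradient batch is an open
question in the underlying framework, so the recorded-log-prob behaviour is
kept simple and documented rather than hidden.

**Intrinsic rewards.** Random network distillation scores the novelty of a
state as the squared error between a frozen random target embedding and a
trained predictor (both one hidden layer of 64 units, embedding dimension
16 — desk-scale defaults). The memory variant keeps a FIFO buffer of 4096
states and rehearses minibatches of 128 from it, which measurably preserves
low novelty on states seen long ago; the memoryless variant trains only on
each incoming batch. The intrinsic reward enters with weight 0.1 by
default, and weight 0 reproduces the no-RND run bit-for-bit because every
stochastic component draws from its own named RNG stream.

**Trainers.** Episodic training rebuilds the environment every episode;
semi-episodic updates every episode but resets the environment only every
`reset_after` episodes (or on a kill); continuous training runs one
persistent engine, updates every fixed number of slices, and *ends* (rather
than resets) when a task raises the kill switch, discarding an incomplete
final block. Checkpoints store parameters, optimizer moments and all RNG
stream states, with floats serialized as `%.17g` strings so a
save/load/continue run is bit-identical to an uninterrupted one.

# Reproducibility

All randomness flows through named streams (engine noise, action sampling,
exploration, RND rehearsal, initialization, evaluation) derived from one
master seed, so toggling one component never perturbs another's draws, and
`(config, seed)` determines every trajectory, metric and checkpoint
bit-exactly. Fixture construction itself (network initialization, initial
particle placement) is a pure function of the fixture seed.

# The synthetic fixtures: what they do and do not show

The fixtures are the package's study conditions. `free-diffusion` and
`abp-gas` (10⁴ particles in the validation runs) exist to compare the
engine against closed forms — passive MSD $4D_t t$, orientation
autocorrelation $e^{-D_r t}$, and the active MSD
$4D_t t + 2v^2\tau_r^2[t/\tau_r + e^{-t/\tau_r} - 1]$ at
$t \in \{0.1, 1, 10\}\,\tau_r$ with $v = 5$, $\tau_r = 1$,
$\Delta t = 0.01$. The `bandit` fixture (2 arms paying 1 and 0, plain
gradient ascent at $\eta = 0.05$, 500 one-slice episodes) validates the
training loop end to end against an environment whose optimum is known.

The `chemotaxis-arena` defaults were chosen once, on physical grounds: a
$20 \times 20$ reflective box with a Gaussian source ($c_0 = 1$, $\sigma_c
= 4$) at its centre; $N = 10$ swimmers started uniformly at least 4 length
units from the walls; $T = 0.1$, $\gamma_t = \gamma_r = 1$, $\Delta t =
0.01$, 5 steps per slice, 20 slices per episode, 300 episodes. The action
set translates at $F_0 = 10$ (half a body-scale length per slice) or turns
at $\tau_0 = 15$ (about 0.75 rad per slice), so a swimmer can reorient in a
couple of slices and cross a meaningful fraction of the arena per episode.
The observable scale (30) and reward scale (10) bring the raw concentration
changes, of order a few hundredths, to order one for the network and the
return statistics.

What passing these tests shows is that the dynamics engine matches ABP
theory, that the training machinery optimizes what it claims to optimize,
and that the full sensing–control–reward loop can learn a
direction-blind chemotaxis strategy distinguishable from the diffusive
null. What it does not show: behaviour under hydrodynamic interactions,
sensor noise and latency of real experiments, wet-lab actuation limits, or
underdamped dynamics — all deliberately out of scope for this engine.

# Known limitations

* The engine is dry (no hydrodynamics) and overdamped only; 3D rotation
  uses a small-angle update that requires $\Delta t \ll \tau_r$.
* The all-pairs WCA force evaluation is $O(N^2)$ per step; the intended
  regime is $N \lesssim 200$ interacting particles (the non-interacting
  validation gases run at $N = 10^4$ without pair forces).
* Discrete action sets only; graph or transformer policies and continuous
  actions are out of scope.
* Episodic rewards are computed per slice; a purely terminal-reward episode
  can be expressed through a task that pays only at the kill switch, but no
  shipped task does so.
```{r}
sessionInfo()
```
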
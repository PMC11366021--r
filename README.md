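# mazelang

Emergent communication between reinforcement-learning agents in grid-world
mazes: teachers compress what they know into low-dimensional messages, a
student acts on those messages, and the package measures what the resulting
"language" encodes.

## The scientific problem

How do internal task representations become a shared code? `mazelang`
implements a teacher-student framework to study this question end to end:

1. **Teachers.** One deep-Q network per maze task learns the state-action
   value function Q(s, a) of a 4x4 grid maze (impenetrable outer walls,
   start fixed at the bottom-left, step reward -0.1, wall bounce -0.5,
   goal +2). Training minimizes the mean squared Bellman residual
   L = mean |Q(s,a) - (R + gamma max_a' Q(s',a'))|^2 over a dual replay
   memory (all unique transitions plus an over-weighted window of the L
   most recent ones), one gradient step per environment step.
2. **Language.** A sparse convolutional autoencoder maps each teacher's
   Q-matrix to a real-valued message m of length K = 5 and back, trained
   with L_SAE = (1-kappa) ||Q' - Q||_2 + kappa ||m||_1. With *student
   feedback* the loss becomes L_SAE + zeta L_goal-finding, so the message
   space is shaped by how useful messages are to the receiver.
3. **Student.** An MLP reads (x, y, m) and outputs action values. Its
   softmax policy induces an absorbing Markov chain over the maze; the
   probability of sitting on the goal after k_opt steps is computed
   analytically and differentiably, giving the goal-finding loss
   (1-gamma) (1 - P[s_k = goal])^4 + gamma ||Q_student||_2 / sqrt(4 n^2).
4. **Analyses.** Within/between-group variance of labeled messages with an
   F test (beta = Var_between / (Var_within + Var_between)), topographic
   similarity (slope of message distance vs meaning distance), binned
   Shannon entropy of 2-PC projections, solve-rate comparisons against
   misinformed students and random walkers, a close-the-loop ("telephone")
   protocol, and language filtering.

## A worked example

```r
library(mazelang)

# the 225 training tasks: all 4x4 mazes with 0 or 1 wall
tasks <- enumerate_training_tasks(4)
length(tasks)
#> [1] 225

# train a teacher on one task and inspect it
task <- tasks[[137]]
task
#> <maze_task 4x4 goal=(3,2) walls: 1,2>
teacher <- train_teacher(task, teacher_config(seed = 5))
teacher
#> <teacher: s_opt=5, converged after 33 episode(s)>

# the greedy policy of the learned Q-matrix is shortest-path optimal
shortest_path_length(task)
#> [1] 5

# compress a Q-matrix into a 5-dimensional message (untrained net here)
lang <- language_net(4, K = 5, seed = 1)
round(encode(lang, q_matrix(teacher)), 3)
#> [1] -0.946  0.148 -0.201  0.134 -0.883

# analytic solve probability of a uniform random walker on this task
round(solve_rate(walker_policy(task, "random"), task), 4)
#> [1] 0.076
```

`run_pipeline(experiment_config(...))` chains the full study: train all
teachers, train languages (with or without feedback), train students on
goal-pattern subsets, evaluate the four agents across scenarios, and write
tidy CSV/JSON artifacts.

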
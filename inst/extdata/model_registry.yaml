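# Mixed-effects model families for log response times.
#
# Each family lists the fixed-effects formula (R syntax, right-hand side)
# and the subset of trials it is fitted on.  All families share the
# response log_rt and the random-effects structure: a random intercept and
# a random slope for (standardized) trial order per subject.  Reference
# levels: sham, pre, verb_generation, low.
families:
  both_tasks_boundary_tms:
    fixed: stimulation * session * boundary
    subset: {}
    description: >-
      TMS-by-session moderation by target-node boundary controllability,
      both tasks pooled.
  task_by_selection_pre:
    fixed: task * entropy_split
    subset: {session: pre}
    description: Baseline task difference in selection costs (median split).
  task_by_retrieval_pre:
    fixed: task * association_split
    subset: {session: pre}
    description: Baseline task difference in retrieval costs (median split).
  boundary_by_entropy_SC:
    fixed: boundary * entropy_c
    subset: {session: pre, task: sentence_completion}
    description: >-
      Boundary controllability moderating baseline selection costs in
      sentence completion (centered continuous entropy).
  modal_by_entropy_SC:
    fixed: modal * entropy_c
    subset: {session: pre, task: sentence_completion}
    description: Modal controllability moderating baseline selection costs.
  boundary_by_association_VG:
    fixed: boundary * association_c
    subset: {session: pre, task: verb_generation}
    description: >-
      Boundary controllability moderating baseline retrieval costs in verb
      generation (centered continuous association strength).
  modal_by_association_VG:
    fixed: modal * association_c
    subset: {session: pre, task: verb_generation}
    description: Modal controllability moderating baseline retrieval costs.
  sham_session_SC:
    fixed: session
    subset: {group: sham, task: sentence_completion}
    description: Session effect in the sham arm, sentence completion.
  sham_session_VG:
    fixed: session
    subset: {group: sham, task: verb_generation}
    description: Session effect in the sham arm, verb generation.
  tms_session_SC:
    fixed: stimulation * session
    subset: {task: sentence_completion}
    description: TMS-by-session effect, sentence completion.
  tms_session_VG:
    fixed: stimulation * session
    subset: {task: verb_generation}
    description: TMS-by-session effect, verb generation.
  tms_session_boundary_SC:
    fixed: stimulation * session * boundary
    subset: {task: sentence_completion}
    description: >-
      Boundary controllability moderating the TMS-by-session effect,
      sentence completion.
  tms_session_boundary_VG:
    fixed: stimulation * session * boundary
    subset: {task: verb_generation}
    description: >-
      Boundary controllability moderating the TMS-by-session effect, verb
      generation.
  trialwise_pre:
    fixed: trial_order_z * entropy_split
    subset: {session: pre, task: sentence_completion}
    description: Trial-order slowing by selection demand, pre-stimulation.
  trialwise_post:
    fixed: trial_order_z * entropy_split
    subset: {session: post, task: sentence_completion}
    description: Trial-order slowing by selection demand, post-stimulation.
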
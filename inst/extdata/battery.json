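[
  {
    "id": "WMCUT_S1",
    "label": "Working Memory Capacity & Updating Task, Subtask 1 (short-term store)",
    "kind": "performance_score",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_better"
  },
  {
    "id": "WMCUT_S2",
    "label": "Working Memory Capacity & Updating Task, Subtask 2 (central executive)",
    "kind": "performance_score",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_better"
  },
  {
    "id": "WMCUT_S3",
    "label": "Working Memory Capacity & Updating Task, Subtask 3 (updating/episodic buffer)",
    "kind": "performance_score",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_better"
  },
  {
    "id": "ACT",
    "label": "Attentional Control Task",
    "kind": "error_count",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_worse"
  },
  {
    "id": "ICT_RST_12",
    "label": "Inhibitory Control & Task/Rule Switching Task, Subtasks 1 & 2",
    "kind": "error_count",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_worse"
  },
  {
    "id": "ICT_RST_SE",
    "label": "Inhibitory Control & Task/Rule Switching Task, switch errors",
    "kind": "error_count",
    "min_score": 0,
    "max_score": null,
    "orientation": "higher_worse"
  },
  {
    "id": "ICT_RST_FS",
    "label": "Inhibitory Control & Task/Rule Switching Task, failed sets",
    "kind": "error_count",
    "min_score": 0,
    "max_score": null,
    "orientation": "higher_worse"
  },
  {
    "id": "CFT",
    "label": "Cognitive Flexibility Task",
    "kind": "error_count",
    "min_score": null,
    "max_score": null,
    "orientation": "higher_worse"
  },
  {
    "id": "CFT2_A",
    "label": "Cognitive Flexibility Task 2, Condition A (errors over 8 sets)",
    "kind": "error_count",
    "min_score": 0,
    "max_score": 8,
    "orientation": "higher_worse"
  },
  {
    "id": "CFT2_B",
    "label": "Cognitive Flexibility Task 2, Condition B (errors over 8 sets)",
    "kind": "error_count",
    "min_score": 0,
    "max_score": 8,
    "orientation": "higher_worse"
  },
  {
    "id": "CFT2_C",
    "label": "Cognitive Flexibility Task 2, Condition C (errors over 8 sets)",
    "kind": "error_count",
    "min_score": 0,
    "max_score": 8,
    "orientation": "higher_worse"
  },
  {
    "id": "VFT",
    "label": "Visual Fluency Task (distinct orderings of 4 pads in 60 s)",
    "kind": "correct_count",
    "min_score": 0,
    "max_score": 24,
    "orientation": "higher_better"
  },
  {
    "id": "EMTW_A",
    "label": "Episodic Memory Task - Windows, Condition A (errors over 15 windows)",
    "kind": "error_count",
    "min_score": 0,
    "max_score": 15,
    "orientation": "higher_worse"
  },
  {
    "id": "EMTW_B",
    "label": "Episodic Memory Task - Windows, Condition B (errors over 15 windows)",
    "kind": "error_count",
    "min_score": 0,
    "max_score": 15,
    "orientation": "higher_worse"
  }
]
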
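{
  "scale_id": "postpartum-mare-pain-scale",
  "version": "1.0",
  "parts": [
    {
      "part_id": 1,
      "name": "Observation of the mare in the stall",
      "part_max": 19,
      "items": [
        {
          "item_id": "posture_weight",
          "label": "Posture and weight distribution",
          "allowed_points": [0, 1, 2, 3, 4],
          "skippable": true
        },
        {
          "item_id": "body_position",
          "label": "Position of the mare's body",
          "allowed_points": [0, 1, 2, 3, 4],
          "skippable": true
        },
        {
          "item_id": "tail_position",
          "label": "Position and movement of the mare's tail",
          "allowed_points": [0, 1],
          "skippable": true
        },
        {
          "item_id": "abdomen_interest",
          "label": "Mare's interest in her abdomen/vulvar area",
          "allowed_points": [0, 2, 4],
          "skippable": true
        },
        {
          "item_id": "vocalization",
          "label": "Vocalization (panting/groaning)",
          "allowed_points": [0, 1],
          "skippable": true
        },
        {
          "item_id": "surroundings_response",
          "label": "Mare's reaction to surroundings and sounds",
          "allowed_points": [0, 2, 4],
          "skippable": true
        },
        {
          "item_id": "sweating",
          "label": "Sweating",
          "allowed_points": [0, 1],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 2,
      "name": "Observation of the mare's facial expression (Horse Grimace Scale)",
      "part_max": 12,
      "items": [
        {
          "item_id": "head_wrinkles",
          "label": "Visibility of wrinkles on the head",
          "allowed_points": [0, 1, 2],
          "skippable": true
        },
        {
          "item_id": "ear_position",
          "label": "Ear position",
          "allowed_points": [0, 1, 2],
          "skippable": true
        },
        {
          "item_id": "eyelids",
          "label": "Eyelids",
          "allowed_points": [0, 1, 2],
          "skippable": true
        },
        {
          "item_id": "nostrils",
          "label": "Nostrils",
          "allowed_points": [0, 1, 2],
          "skippable": true
        },
        {
          "item_id": "lip_retraction",
          "label": "Turning back the lips / teeth gnashing",
          "allowed_points": [0, 2],
          "skippable": true
        },
        {
          "item_id": "tongue_protrusion",
          "label": "Tongue protruding",
          "allowed_points": [0, 2],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 3,
      "name": "Clinical examination",
      "part_max": 4,
      "items": [
        {
          "item_id": "respiratory_rate",
          "label": "Respiratory rate",
          "allowed_points": [0, 1, 2],
          "skippable": true
        },
        {
          "item_id": "body_temperature",
          "label": "Body temperature",
          "allowed_points": [0, 1, 2],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 4,
      "name": "Palpation of the mammary gland and body torso",
      "part_max": 3,
      "items": [
        {
          "item_id": "back_loin_croup",
          "label": "Back, loin and croup (swelling / increased warmth)",
          "allowed_points": [0, 1],
          "skippable": true
        },
        {
          "item_id": "abdomen_flank",
          "label": "Abdomen and flank (swelling / increased warmth)",
          "allowed_points": [0, 1],
          "skippable": true
        },
        {
          "item_id": "udder",
          "label": "Udder (swelling / increased warmth)",
          "allowed_points": [0, 1],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 5,
      "name": "Peristalsis examination",
      "part_max": 1,
      "items": [
        {
          "item_id": "fecal_output",
          "label": "Fecal output",
          "allowed_points": [0, 1],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 6,
      "name": "Hoof examination",
      "part_max": 2,
      "items": [
        {
          "item_id": "hoof_left_front",
          "label": "Left front hoof temperature",
          "allowed_points": [0, 0.5],
          "skippable": true
        },
        {
          "item_id": "hoof_left_hind",
          "label": "Left hind hoof temperature",
          "allowed_points": [0, 0.5],
          "skippable": true
        },
        {
          "item_id": "hoof_right_front",
          "label": "Right front hoof temperature",
          "allowed_points": [0, 0.5],
          "skippable": true
        },
        {
          "item_id": "hoof_right_hind",
          "label": "Right hind hoof temperature",
          "allowed_points": [0, 0.5],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 7,
      "name": "Food test",
      "part_max": 2,
      "items": [
        {
          "item_id": "treat_reaction",
          "label": "Reaction to tasty treats",
          "allowed_points": [0, 1, 2],
          "skippable": true
        }
      ]
    },
    {
      "part_id": 8,
      "name": "Examination of walking traits",
      "part_max": 4,
      "items": [
        {
          "item_id": "gait_behavior",
          "label": "Behavior in motion",
          "allowed_points": [0, 2, 4],
          "skippable": true
        }
      ]
    }
  ],
  "total_max": 47
}
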
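{
  "format_version": "1.0",
  "description": "Leading-eight social norms plus unconditional strategies: assessment rule d(ra, rp, b) and action rule b(ra, rp); 1 = good/cooperate, 0 = bad/defect. Keys encode the context, e.g. raG|rpB|bC = good donor, bad recipient group, observed cooperation.",
  "strategies": [
    {
      "id": "L1",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 1,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 1,
        "raB|rpB|bD": 0
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 1
      }
    },
    {
      "id": "L2",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 0,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 1,
        "raB|rpB|bD": 0
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 1
      }
    },
    {
      "id": "L3",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 1,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 1,
        "raB|rpB|bD": 1
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "L4",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 1,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 0,
        "raB|rpB|bD": 1
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "L5",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 0,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 1,
        "raB|rpB|bD": 1
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "L6",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 0,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 0,
        "raB|rpB|bD": 1
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "L7",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 1,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 0,
        "raB|rpB|bD": 0
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "L8",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 0,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 0,
        "raB|rpB|bD": 0
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 0,
        "raB|rpG": 1,
        "raB|rpB": 0
      }
    },
    {
      "id": "ALLC",
      "assessment": {
        "raG|rpG|bC": 1,
        "raG|rpG|bD": 1,
        "raG|rpB|bC": 1,
        "raG|rpB|bD": 1,
        "raB|rpG|bC": 1,
        "raB|rpG|bD": 1,
        "raB|rpB|bC": 1,
        "raB|rpB|bD": 1
      },
      "action": {
        "raG|rpG": 1,
        "raG|rpB": 1,
        "raB|rpG": 1,
        "raB|rpB": 1
      }
    },
    {
      "id": "ALLD",
      "assessment": {
        "raG|rpG|bC": 0,
        "raG|rpG|bD": 0,
        "raG|rpB|bC": 0,
        "raG|rpB|bD": 0,
        "raB|rpG|bC": 0,
        "raB|rpG|bD": 0,
        "raB|rpB|bC": 0,
        "raB|rpB|bD": 0
      },
      "action": {
        "raG|rpG": 0,
        "raG|rpB": 0,
        "raB|rpG": 0,
        "raB|rpB": 0
      }
    }
  ]
}
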
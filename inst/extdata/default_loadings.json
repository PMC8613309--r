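{
  "activity": {
    "locomotion_s": 1, "not_hanging_s": 1, "exploration_rate": 1,
    "ate_food": 1, "drank_water": 1, "crouching": 1
  },
  "emotionality": {
    "cooing_rate": 1, "barking_rate": 1,
    "scratched": 1, "threats": 1, "lipsmacked": 1
  }
}
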
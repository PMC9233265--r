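{
  "framings": {
    "LT40": [
      "Hi, {name}! You did around {steps} steps so far and reached {pct}% of your goal for today. There is still plenty of day left - a walk right now would get you moving! Interesting fact: {benefit}",
      "Hey {name}, {steps} steps so far puts you at {pct}% of today's goal. Every journey starts with a single step - how about a stroll after class? Did you know: {benefit}",
      "Hello {name}! With {steps} steps you are at {pct}% of your daily goal. A quick walk around the block could change that fast. Remember: {benefit}",
      "Hi {name}, today you have {steps} steps, {pct}% of your goal. The afternoon is yours - put on your shoes and get some fresh air! Fun fact: {benefit}",
      "Hey {name}! {steps} steps so far means {pct}% of your goal. No pressure - even 10 active minutes count. Worth knowing: {benefit}",
      "Hi {name}, you are at {pct}% of your goal with {steps} steps. Meeting a friend for a walk could be fun and active at once. By the way: {benefit}"
    ],
    "GE40": [
      "Hi, {name}! You did around {steps} steps so far and reached {pct}% of your goal for today - a solid start, keep it rolling! Interesting fact: {benefit}",
      "Hey {name}, {steps} steps already - that is {pct}% of today's goal. You are warming up nicely; an evening walk would push you further. Did you know: {benefit}",
      "Hello {name}! {pct}% of your goal done with {steps} steps. Nice pace - a bit more movement and you will pass the halfway mark. Remember: {benefit}",
      "Hi {name}, you have {steps} steps, {pct}% of your goal. Good momentum - why not take the stairs and the long way home today? Fun fact: {benefit}",
      "Hey {name}! {steps} steps so far, {pct}% of the goal. You are on your way - keep the streak going this afternoon. Worth knowing: {benefit}"
    ],
    "GE60": [
      "Hi, {name}! You did around {steps} steps so far and reached {pct}% of your goal for today - well over half way, great going! Interesting fact: {benefit}",
      "Hey {name}, {steps} steps puts you at {pct}% of today's goal. The finish line is in sight - one good walk seals it. Did you know: {benefit}",
      "Hello {name}! {pct}% of your daily goal reached with {steps} steps. Strong effort - keep moving and today is yours. Remember: {benefit}",
      "Hi {name}, {steps} steps so far and {pct}% of the goal done. You clearly got going today - finish strong! Fun fact: {benefit}",
      "Hey {name}! With {steps} steps you are at {pct}% of your goal. Most of the work is done - a short evening stroll will do the rest. Worth knowing: {benefit}"
    ],
    "GE80": [
      "Hi, {name}! You did around {steps} steps so far and reached {pct}% of your goal for today - good job, can you do even better? Interesting fact: {benefit}",
      "Hey {name}, {steps} steps already - {pct}% of today's goal. So close! A few more active minutes and you are there. Did you know: {benefit}",
      "Hello {name}! {pct}% of your goal with {steps} steps - impressive. One last push and you can tick today off. Remember: {benefit}",
      "Hi {name}, {steps} steps so far means {pct}% of your goal. Almost there - walk the dog, fetch the groceries, anything counts! Fun fact: {benefit}",
      "Hey {name}! You are at {pct}% with {steps} steps. The goal is within reach tonight - go get it! Worth knowing: {benefit}"
    ],
    "GE100": [
      "Hi, {name}! You did around {steps} steps so far and reached {pct}% of your goal for today - goal smashed, amazing work! Interesting fact: {benefit}",
      "Hey {name}, {steps} steps - that is {pct}% of today's goal. Goal complete! Anything extra now is a bonus for tomorrow's you. Did you know: {benefit}",
      "Hello {name}! {pct}% of your goal reached with {steps} steps. Fantastic - you beat your personal target today. Remember: {benefit}",
      "Hi {name}, {steps} steps and {pct}% of the goal - outstanding! Celebrate with a relaxed walk or some stretching. Fun fact: {benefit}",
      "Hey {name}! {steps} steps, {pct}% of your goal - you are on fire today. Keep this energy for the rest of the week! Worth knowing: {benefit}"
    ]
  },
  "benefits": [
    "physical activity benefits improved concentration, so if you are active, you may get better study results!",
    "regular activity strengthens your heart and can boost your stamina for sports and everyday life.",
    "being active during the day is linked with better sleep at night.",
    "active breaks reduce stress and can lift your mood within minutes.",
    "building activity habits now makes it much easier to stay fit as an adult.",
    "movement keeps bones and muscles strong while they are still growing.",
    "regular walks can improve creativity - many people get their best ideas on the move.",
    "active time with friends counts double: fitness plus social time."
  ]
}
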
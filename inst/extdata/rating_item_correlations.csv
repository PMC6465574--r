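item,amusement,awe,gratitude,hope,inspiration,interest,joy,love,pride,serenity,arousal,valence,familiarity,liking
amusement,1,-0.48,-0.05,0.12,0.27,0.81,0.88,0.14,0.03,-0.2,0.62,0.63,0.43,0.69
awe,-0.48,1,0.56,0.44,0.47,-0.05,-0.23,-0.14,0.62,0.3,-0.02,0.07,0.02,0.06
gratitude,-0.05,0.56,1,0.94,0.87,0.36,0.31,0.51,0.85,0.5,0.09,0.68,0.33,0.59
hope,0.12,0.44,0.94,1,0.94,0.51,0.48,0.59,0.83,0.46,0.19,0.79,0.41,0.71
inspiration,0.27,0.47,0.87,0.94,1,0.66,0.6,0.41,0.89,0.3,0.42,0.85,0.53,0.81
interest,0.81,-0.05,0.36,0.51,0.66,1,0.92,0.26,0.45,0.11,0.56,0.85,0.51,0.92
joy,0.88,-0.23,0.31,0.48,0.6,0.92,1,0.38,0.41,0.06,0.58,0.86,0.53,0.89
love,0.14,-0.14,0.51,0.59,0.41,0.26,0.38,1,0.34,0.45,-0.11,0.5,-0.02,0.41
pride,0.03,0.62,0.85,0.83,0.89,0.45,0.41,0.34,1,0.37,0.31,0.68,0.48,0.64
serenity,-0.2,0.3,0.5,0.46,0.3,0.11,0.06,0.45,0.37,1,-0.56,0.31,-0.02,0.2
arousal,0.62,-0.02,0.09,0.19,0.42,0.56,0.58,-0.11,0.31,-0.56,1,0.42,0.5,0.53
valence,0.63,0.07,0.68,0.79,0.85,0.85,0.86,0.5,0.68,0.31,0.42,1,0.58,0.94
familiarity,0.43,0.02,0.33,0.41,0.53,0.51,0.53,-0.02,0.48,-0.02,0.5,0.58,1,0.58
liking,0.69,0.06,0.59,0.71,0.81,0.92,0.89,0.41,0.64,0.2,0.53,0.94,0.58,1
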
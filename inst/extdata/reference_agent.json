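{"genome":[0.965408264783131,0.0404084962556835,0.276381192796742,0.713036702783878,0.0265513713102098,0.189920049403993,0.279323980262828],"seed":16,"fitness":0.957153734684733}
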
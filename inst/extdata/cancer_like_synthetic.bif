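network unknown {
  property class Cancer ;
}
variable Pollution {
  type discrete [ 2 ] { low, high };
}
variable Smoker {
  type discrete [ 2 ] { True, False };
}
variable Cancer {
  type discrete [ 2 ] { True, False };
}
variable Xray {
  type discrete [ 2 ] { positive, negative };
}
variable Dyspnoea {
  type discrete [ 2 ] { True, False };
}
probability ( Pollution ) {
  table             0.85,             0.15;
}
probability ( Smoker ) {
  table             0.35,             0.65;
}
probability ( Cancer | Pollution, Smoker ) {
  ( low, True )              0.1,              0.9;
  ( low, False )             0.02,             0.98;
  ( high, True )              0.3,              0.7;
  ( high, False )             0.08,             0.92;
}
probability ( Xray | Cancer ) {
  ( True )              0.9,              0.1;
  ( False )             0.15,             0.85;
}
probability ( Dyspnoea | Cancer ) {
  ( True )              0.7,              0.3;
  ( False )             0.25,             0.75;
}
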
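network unknown {
  property class Either ;
}
variable VisitAsia {
  type discrete [ 2 ] { True, False };
}
variable Smoking {
  type discrete [ 2 ] { True, False };
}
variable Tuberculosis {
  type discrete [ 2 ] { True, False };
}
variable LungCancer {
  type discrete [ 2 ] { True, False };
}
variable Bronchitis {
  type discrete [ 2 ] { True, False };
}
variable Either {
  type discrete [ 2 ] { True, False };
}
variable Xray {
  type discrete [ 2 ] { True, False };
}
variable Dyspnoea {
  type discrete [ 2 ] { True, False };
}
probability ( VisitAsia ) {
  table             0.05,             0.95;
}
probability ( Smoking ) {
  table              0.5,              0.5;
}
probability ( Tuberculosis | VisitAsia ) {
  ( True )              0.2,              0.8;
  ( False )             0.02,             0.98;
}
probability ( LungCancer | Smoking ) {
  ( True )             0.25,             0.75;
  ( False )             0.03,             0.97;
}
probability ( Bronchitis | Smoking ) {
  ( True )              0.6,              0.4;
  ( False )              0.3,              0.7;
}
probability ( Either | Tuberculosis, LungCancer ) {
  ( True, True )             0.98,             0.02;
  ( True, False )             0.95,             0.05;
  ( False, True )             0.95,             0.05;
  ( False, False )             0.02,             0.98;
}
probability ( Xray | Either ) {
  ( True )             0.95,             0.05;
  ( False )              0.1,              0.9;
}
probability ( Dyspnoea | Bronchitis, Either ) {
  ( True, True )             0.95,             0.05;
  ( True, False )              0.8,              0.2;
  ( False, True )              0.7,              0.3;
  ( False, False )              0.1,              0.9;
}
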
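country,stratum,survey_label,tfr,wanted_tfr,cpr,natural_tfr
Kenya,national,2014,3.9,3.1,,9.6
Kenya,national,2008–09,4.6,3.2,,8.6
Kenya,national,2003,4.9,3.6,,8.2
Kenya,national,1998,4.7,3.3,,7.8
Kenya,national,1993,5.4,3.6,,8.1
Kenya,national,1989,6.7,4.1,,9.2
Rwanda,national,2014–15,4.2,3.3,,9.2
Rwanda,national,2010,4.6,3.3,,9.7
Rwanda,national,2007–08,5.5,3.8,,8.8
Rwanda,national,2005,6.1,4.4,,7.4
Rwanda,national,2000,5.8,4.6,,6.7
Rwanda,national,1992,6.2,4.7,,7.9
Tanzania,national,2015–16,5.2,4.5,,8.6
Tanzania,national,2010,5.4,4.6,,8.3
Tanzania,national,2004–05,5.7,4.8,,7.8
Tanzania,national,1999,5.6,4.8,,7.6
Tanzania,national,1996,5.8,4.8,,7.1
Tanzania,national,1991–92,6.2,5.4,,6.9
Uganda,national,2011,6.2,4.4,,8.9
Uganda,national,2006,6.7,4.7,,8.8
Uganda,national,2000–01,6.9,5.0,,9.0
Uganda,national,1995,6.9,5.3,,8.1
Uganda,national,1988–89,7.4,6.2,,7.8
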
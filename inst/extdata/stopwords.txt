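a
an
the
this
that
these
those
he
she
it
they
them
we
us
you
i
me
his
her
its
their
our
your
my
and
or
but
nor
so
yet
for
of
to
in
on
at
by
with
from
as
is
are
was
were
be
been
being
am
have
has
had
do
does
did
will
would
shall
should
may
might
must
can
could
not
no
if
then
than
because
while
about
into
over
under
very
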